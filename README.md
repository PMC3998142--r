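# sigscan

A desk-scale protein function classification framework in R. `sigscan`
answers the question a genome annotator asks of every new sequence set:
*which known signatures — sequence patterns, scoring profiles — match each
protein, which curated entries do those signatures belong to, and what
Gene Ontology terms and pathways follow?* It is built for people who want
the full architecture of a production signature-scanning pipeline —
dependency-scheduled jobs, chunked parallel execution, checksum-keyed
result caching, multi-format output, nucleotide input via six-frame ORF
translation — in a self-contained package with no external binaries,
licensed model files or network services.

## What it computes

* **Signature scanning.** Two analyzer modalities behind one contract:
  single-pass predictors, and scan + post-process pipelines. Built-in
  models are PROSITE-style patterns (`W-H-x(2)-C-C`, `[DE]-x-K`, anchors
  `<`/`>`, repeats `(n)`/`(n,m)`) matched by a backtracking automaton that
  reports every start position with its shortest accepting window, and
  position-specific scoring profiles (an *L*×20 matrix; a window at
  position *i* scores `sum_j M[j, s(i+j-1)]` and is reported when the sum
  meets the threshold).
* **Post-processing.** Raw hits from signatures in the same clan that
  overlap by ≥ 1 residue compete; only the best survives (highest score,
  then smaller start, then lexicographically smaller accession). Losers
  are re-statused, never deleted.
* **Annotation.** Matches are joined to curated entries, their GO terms,
  and pathway cross-references. A pathway is associated with an entry when
  strictly more than 80% of the entry's matched reference proteins carry
  that pathway annotation.
* **Execution.** Each analysis is a declarative job of dependency-wired
  steps; chunkable steps are bound to sequence chunks and run by a master
  that dispatches to workers (serial or forked multiprocess mode) with
  retries, demand-driven spawning and tiered worker topology. Serial and
  multiprocess runs are byte-identical.
* **Caching.** Results are keyed by the MD5 of the canonical residue
  string; a store built from prior result XML short-circuits
  recomputation, guarded by a signature-release version stamp.
* **Nucleotide input.** Six-frame, stop-to-stop ORF discovery (complete
  ORFs, standard genetic code), scanning of the translated proteins, and
  exact back-projection of protein-coordinate matches onto the parent
  nucleotide sequence in GFF3.
* **Output.** TSV (15 columns), canonical lossless XML, GFF3 (with
  `##FASTA` section), JSON — plus a `convert` mode that regenerates any
  projection from the XML, byte-identical to writing it directly.

## Worked example

Everything below is generated — the fixture generator plants motifs at
known coordinates and records the ground truth, so the run is fully
reproducible:

```r
library(sigscan)
fx  <- generate_fixture(default_fixture_spec(seed = 1), "demo")
cfg <- list(input = fx$fasta, data_dir = fx$data_dir,
            output_base = "demo/run", date = "2000-01-01",
            disable_precalc = TRUE)
res <- run_pipeline(cfg)
head(readLines("demo/run.tsv"), 2)
```

```
prot002  c8b5c3d3458711c16613ec4af8a703fc  266  toylib  TOY00001  tryptophan sandwich motif  130  135  -  filtered_in  2000-01-01  ENT00001  Tryptophan sandwich superfamily  GO:0003824|GO:0008152  KEGG:K00001
prot006  acbfa6861d7c9269214cf4c2b6d33f86  113  toylib  TOY00002  acidic linker pattern  72  76  -  filtered_in  2000-01-01  ENT00002  Acidic linker domain  GO:0005515  -
```

Reading a row: protein `prot002` (checksum, length 266) matched signature
`TOY00001` of library `toylib` at residues 130–135; the match survived
post-processing (`filtered_in`), belongs to entry `ENT00001` with two GO
terms, and that entry is associated with KEGG pathway K00001 because more
than 80% of its reference proteins carry it. The same run writes
`run.xml`, `run.gff3` and `run.json`; with ten planted motifs the TSV has
exactly ten rows — the fixture's ground truth table (`fx$ground_truth`)
lists the same ten `(protein, signature, start, stop)` tuples.

The same pipeline is available from a shell via the bundled wrapper:

```sh
Rscript inst/scripts/sigscan -i demo/proteins.fasta --datadir demo \
    -f TSV,XML -b demo/cli_run --disable-precalc
Rscript inst/scripts/sigscan --convert demo/cli_run.xml -f GFF3 -b demo/cli_run
```

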