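---
title: "sigscan: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sigscan: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscan)
```

`sigscan` is a complete, desk-scale signature-scanning architecture: a
data model for sequences, signatures, entries and matches; a dependency
scheduler with chunked master/worker execution; pluggable analyzers; a
checksum-keyed match cache; and a family of output formats with XML as
the canonical, lossless form. This vignette records the scientific
conventions the package commits to, the parameters that matter, and the
reasoning behind design choices that were genuinely open.

## The data model

A protein is canonicalized before anything else: whitespace stripped,
residues uppercased, a single trailing `*` (the stop emitted by
translation) removed. The canonical residue string is then hashed (MD5,
lowercase hex) and that checksum — never the user-supplied identifier —
keys all downstream computation. Two consequences follow. First,
duplicated sequences are analyzed once and results are fanned back out to
every submitted identifier. Second, a store of previously computed
matches can be queried by checksum alone, which is what makes the lookup
cache sound. MD5 was chosen because it is the de facto convention for
sequence cross-referencing and trivially verifiable with external tools;
collision resistance is irrelevant here — the hash is an index, not a
security boundary.

Ambiguity and rare codes (`B`, `Z`, `X`, `U`, `O`) are accepted and passed
through unchanged; each analyzer decides how to treat them (the built-in
profile scorer gives them 0 at every position; patterns match them only
via explicit set membership or a negated set that excludes them). An
internal `*` is an error rather than a silent truncation: in practice it
signals a frame-shifted or mistranslated input the user should see.

## Analyzers

Scanning applications in this field come in two shapes: single-algorithm
predictors whose raw output is the result, and multi-model searches whose
raw output must be post-processed before it is reportable. `sigscan`
encodes that distinction as a two-stage contract — `scan(proteins,
signatures)` then `postprocess(matches, signatures)` — with the
guarantees that scanning is pure per (protein, signature) and that
post-processing only sets match status, never invents or deletes
locations. Keeping losers in the data (as `filtered_out`) rather than
deleting them makes post-processing idempotent and auditable.

### Pattern models

Patterns use PROSITE-like syntax: elements separated by `-`, each a
literal residue, the wildcard `x`, a set `[DE]` or negated set `{P}`,
optionally repeated `(n)` or `(min,max)`; `<` and `>` anchor to the
termini. The matcher is a memoized backtracking automaton over the parsed
element list. Variable repeats make "the" match window ambiguous; the
package resolves this deterministically: every distinct start position at
which the pattern can accept is reported, each with its shortest
accepting window. The test suite checks this semantics against a
brute-force oracle that expands the pattern to a regular expression and
tries every (start, length) pair explicitly, over a thousand random
pattern/sequence draws.

### Profile models

A profile is an *L*×20 score matrix plus a threshold; a window scores the
sum of per-position scores for its residues (unknown residues score 0)
and every window at or above threshold is reported with its score, with
no non-maximum suppression at the raw stage — overlap handling is
post-processing's job. This is deliberately the simplest member of the
profile/HMM family: the framework around it (chunking, retries, caching,
annotation) is the subject of this package, not the scoring function, and
the scanner is oracle-tested against exhaustive window sums.

### Overlap resolution

The built-in post-processor implements clan-based filtering: signatures
may carry a clan label; within a clan, locations overlapping by at least
one residue compete, and the best survives — highest score, ties to the
smaller start, then to the lexicographically smaller accession (a missing
score ranks below any number, so scoreless pattern hits lose to scored
profile hits when they collide within a clan). A multi-location match
competes location-wise and survives if any location survives. Clanless
signatures never compete. This greedy best-first rule is an explicit,
documented stand-in for the heterogeneous post-processing of real member
databases; it is deterministic, idempotent and conserves match count,
which is what the architecture requires of any post-processor.

## ORF discovery and coordinate back-mapping

Nucleotide input is scanned in all six reading frames for maximal
stop-free codon runs, and a run is reported as an ORF only when it is
terminated by a stop codon; the stop is included in the ORF's nucleotide
span but excluded from the protein. Unterminated runs at a frame's end
are not reported — requiring a complete ORF makes every reported protein
a fully bounded translation unit and gives back-projection an exact,
unambiguous anchor. The trade-off (a true coding region running off a
contig edge is missed) is acceptable for the synthetic and desk-scale
inputs this package targets, and is the documented convention rather than
a claim about biology. Translation uses the standard genetic code only;
codons containing `N` translate to `X`. The default
`min_protein_length = 50` mirrors common ORF-finder defaults; the
fixtures use 30 so that shorter planted proteins remain testable.

Back-mapping is pure codon arithmetic on 1-based inclusive forward-strand
coordinates. For a `+` ORF, residue interval \[s, e\] maps to
`nt_start + 3(s-1) .. nt_start + 3e - 1`; for a `-` ORF, reading proceeds
from `nt_end` downward, so the interval maps to
`nt_end - 3e + 1 .. nt_end - 3(s-1)`. Two invariants are enforced by
property tests: the projected span is always exactly `3 (e - s + 1)`
bases, and translating the projected bases (reverse-complemented for `-`)
reproduces the residue interval — checked on a thousand random
ORF/interval draws per run, plus a strand-flip oracle
(`find_orfs(revcomp(s))` must mirror `find_orfs(s)`).

## The job engine

Each analysis is declared as a job whose steps carry explicit
dependencies; merging (fan-in) and branching (fan-out) are both
expressible. Planning binds chunkable steps to chunks of the deduplicated
checksum list — `ceil(n / chunk_size)` instances per chunkable step, all
chunks but the last exactly `chunk_size` — and derives instance-level
edges: chunk-aligned between chunkable steps, fan-in into non-chunkable
steps. Cycles are detected at planning time and named in the error.

The master dispatches instances whose dependencies are done. Serial mode
executes in-process in a deterministic topological order (ties broken by
job name, step name, chunk index), which makes serial output
byte-identical across runs and the baseline for every equivalence check.
Multiprocess mode realizes the request-queue contract with an in-process
pool of forked workers: workers are spawned on demand (when the ready
backlog exceeds idle capacity), attach directly to the master until
`max_direct_workers` children exist and to an existing worker thereafter
— forming tiers — and expire after `worker_lifetime` idle seconds. The
tier structure is tracked as an explicit topology in the execution
report; process launching sits behind a small launcher so a cluster
submission mechanism could be slotted in without touching scheduling
logic. Failures (a raised error, or a worker that dies without replying)
re-queue the instance until `retry_limit` total attempts, after which the
run aborts carrying the failing instance and its diagnostics. A
fault-injection hook in the worker policy lets tests kill a real forked
worker mid-step deterministically.

Safety rests on step idempotence: every step writes to an
instance-scoped temporary path and atomically renames on completion, so
at-least-once delivery and retries cannot corrupt results — re-executing
a completed instance rewrites the same bytes. Intermediate artifacts pass
by path under a run-scoped work directory (a shared-filesystem
assumption, matching the deployment shape this architecture comes from).

Defaults: `chunk_size` 1000, `max_direct_workers` 4, `retry_limit` 2
(one retry), backlog threshold 0 (spawn as soon as ready work outruns
idle workers), `worker_lifetime` 30 s. None of these is prescribed by the
underlying method; they are desk-scale values exposed in the single
configuration file.

## Match lookup

A `match_store` maps checksums to match sets and carries a version stamp
(the sorted `library:version` pairs it was computed with). Partitioning
returns store hits verbatim and leaves the rest for analysis; any stamp
mismatch voids the whole store — per-library partial reuse is
deliberately out of scope because mixing match sets computed under
different releases silently changes results. A corrupt or unreadable
store degrades to all-miss with a warning: the cache is an optimization
and must never be a correctness dependency. The store's on-disk form is a
single XML file (either a prior run's result XML or the compact
`match-store` dialect), so cache transparency is testable end to end: a
run replayed entirely from a store must be byte-identical to the run that
produced it, and the test suite and acceptance script both assert exactly
that.

## Output formats

The XML document is canonical: reading it back reconstructs the in-memory
document field-for-field, and TSV, GFF3 and JSON are projections of that
document. The `convert` operation therefore guarantees byte-equality with
the direct writers — asserted on randomized documents. Ordering is fixed
everywhere (proteins by first identifier, matches by analysis, accession
and start; TSV rows likewise), scores print with one fixed decimal in TSV
and full precision (`%.17g`) in XML so they survive the round trip, and
the run date is injectable so whole-output byte comparisons are possible;
with a pinned date, a given configuration and input yields identical
bytes every run. GFF3 for nucleotide runs emits one feature per ORF that
has matches plus one projected `protein_match` feature per location, so
projected lines always have a visible parent feature.

## The fixture generator

Synthetic data is a first-class module, not a test convenience. A fixture
spec (seed, protein count, length range, placements, library, entry and
pathway tables) generates: background proteins drawn uniformly from the
20-letter alphabet, planted motif occurrences at recorded coordinates
(patterns realized at minimal repeat counts, profiles as their argmax
string), a signature library bundle, an integration bundle, and a ground
truth table. The generator **rejection-samples** every protein: a draw is
accepted only when the pipeline's filtered-in matches on it equal the
planted expectation exactly, so ground-truth precision and recall are
exact properties of the fixture, not probabilistic hopes. The default
study fixture is 50 proteins of 100–300 residues with 10 planted
occurrences cycling through the library (two clanned models, one clanless,
one unintegrated); reference annotation tables place 10 proteins per
entry with a 90% pathway annotation fraction for the first entry, so the
strict >80% rule associates exactly one pathway. Boundary probes (81%,
80%, 79% over 100 reference proteins) are separate specs used by the
tests and the acceptance script.

Nucleotide fixtures embed each planted protein's coding sequence —
reverse-translated with randomly drawn synonymous codons — between
in-frame stop codons, on a random strand, inside random flanks. Expected
nucleotide projections are computed arithmetically from the construction
(flank lengths and codon positions), independently of the ORF finder, and
the whole contig is rejection-sampled against spurious ORF matches.
Randomizing codon choice matters: with a fixed reverse translation, a
spurious cross-frame match inside the coding region would survive any
amount of flank resampling.

What the fixtures do **not** emulate: realistic residue composition,
homology, low-complexity regions, fragmented or partial ORFs, and
realistic signature densities. Passing tests therefore demonstrate that
the machinery is correct — exact recovery, determinism, cache and
parallel transparency — not that the toy models have biological power on
real proteomes.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run at deliberately small
scale: the study fixture is 50 proteins / 10 plants; engine tests use
diamond plans over 3 chunks and demand-5 worker pools; oracle comparisons
use 1000 random cases per scanner and 1000 random ORF intervals;
serial/multiprocess equivalence runs over 5 seeded fixtures. These sizes
were chosen as the smallest that exercise every code path several times
over; all quantities they measure are exact (match sets, byte equality,
counts), so larger inputs would not change any asserted value. All
scores are plain double sums of small matrices — no tolerance tuning is
needed anywhere; equality assertions are exact except where scores print
at fixed decimal precision, which is part of the format definition.

## Known limitations

* Single-host execution only; the queue contract and launcher are the
  extension points for a real broker or cluster scheduler, but none ships.
* No real profile/HMM calibration (no e-values); the `evalue` slot exists
  in the data model and formats but the built-in analyzers never set it.
* Pattern syntax omits nested groups and PROSITE's rarely used
  skip-flag conventions.
* The lookup store is all-or-nothing per release stamp; no per-library
  partial reuse.
* Alternative genetic codes, splicing and partial ORFs are out of scope.
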