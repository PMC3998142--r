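# Default run configuration. Every key can be overridden on the command
# line; editing this single file reconfigures the tool.
seq_type: p            # p = protein, n = nucleotide input
formats: [tsv, xml, gff3, json]
analyses: ~            # ~ = all libraries found under <data_dir>/libraries
chunk_size: 1000       # sequences per chunk
mode: serial           # serial | multiprocess
max_workers: 4         # worker cap in multiprocess mode
max_direct_workers: 4  # direct children per parent before tiering
retry_limit: 2         # executions per step instance (1 retry)
min_orf_length: 50     # residues; six-frame stop-to-stop ORF filter
disable_precalc: false
lookup: ~              # path to a match-store or result XML
date: ~                # ~ = today; set to pin the run date in outputs
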