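# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".cl", ".N", ".SD", "accession", "alt_seq", "bad", "carriers",
  "carriers_str", "category", "chrom", "context", "context3", "end",
  "gene_id", "group", "gstart", "i.N", "id", "k", "linked_gene", "length",
  "members", "mode", "n", "n_clusters", "n_genes", "nmembers", "pos",
  "sample_id", "slot_start", "source_haplotype", "span", "start", "status",
  "stage", "sv", "sv_count", "sv_id", "svtype", "total", "truncated", "win",
  "DEL", "INS", "INV", "TRA", "where", "rep", "locus_id"
))
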