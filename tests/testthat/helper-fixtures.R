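# Worked-example fixture: four binding sites of one TF, the reference
# greedy (sorted) alignment of them, and an alignment of the same sites
# produced by a general-purpose progressive aligner.

demo_sequences <- c(
  s1 = "ACCTAAGCTG",
  s2 = "ATTACACCAAGTACC",
  s3 = "GGAATTTCCTGTTGATCC",
  s4 = "CTAAAGGACGTCACATTGC"
)

demo_site_set <- function() {
  site_set("TFdemo", "demo", names(demo_sequences), unname(demo_sequences))
}

demo_sorted_rows <- c(
  s1 = "-------ACCTAAGCTG--",
  s2 = "----ATTACACCAAGTACC",
  s3 = "-GGAATTTCCTGTTGATCC",
  s4 = "CTAAAGGACGTCACATTGC"
)
demo_sorted_consensus <- "----A--AC-T-A--T--C"

demo_clustal_rows <- c(
  s2 = "-------ATTACACCAAGTACC",
  s3 = "----GGAATTTCCTGTTGATCC",
  s1 = "-------ACCTAA-GCTG----",
  s4 = "CTAAAGGACGTCACATTGC---"
)
demo_clustal_consensus <- "-------A--TCA---TG----"

write_demo_table <- function(path) {
  lines <- c("species\ttf_id\tsite_id\tsequence",
             sprintf("demo\tTFdemo\t%s\t%s",
                     names(demo_sequences), unname(demo_sequences)))
  writeLines(lines, path)
  path
}

# Small random site set for property tests.
random_site_set <- function(n_sites = 5, min_len = 4, max_len = 12,
                            tf_id = "TFr", species = "rand") {
  lens <- sample(min_len:max_len, n_sites, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  site_set(tf_id, species, sprintf("r%d", seq_len(n_sites)), seqs)
}

# Random trained model from a random alignment.
random_model <- function(n_sites = 4, min_len = 4, max_len = 12) {
  consensus_from_alignment(sorted_align(random_site_set(n_sites, min_len, max_len)))
}
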