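# Shared fixtures: small designs and FASTQ writers built in code.

toy_scaffold <- function(name = "toy", arm5 = "GGCGGCG", arm3 = "CGCCGCC") {
  scaffold_spec(name, arm5, arm3)
}

# the two-scaffold CDE-style example design shipped with the package
cde_design <- function(loop_lengths = NULL) {
  d <- read_pool_design(system.file("extdata", "synthetic_cde_design.yaml",
                                    package = "srbns"))
  if (is.null(loop_lengths)) d else pool_design(d$scaffolds, loop_lengths)
}

ade_design <- function() {
  read_pool_design(system.file("extdata", "synthetic_ade_design.yaml",
                               package = "srbns"))
}

# write reads (RNA or DNA strings) as a minimal FASTQ file
write_test_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- if (length(reads)) {
    as.vector(rbind(paste0("@r", seq_along(reads)),
                    chartr("U", "T", reads),
                    rep("+", length(reads)),
                    strrep("I", nchar(reads))))
  } else character(0)
  writeLines(lines, path)
  path
}

# count table from explicit (scaffold, loop, count) triples
manual_counts <- function(scaffold, loop, count, condition = "input") {
  df <- data.frame(condition = condition, scaffold = scaffold, loop = loop,
                   count = as.integer(count), stringsAsFactors = FALSE)
  structure(df,
            qc = c(reads = sum(count), assigned = sum(count),
                   unassigned = 0L, invalid_loop_length = 0L),
            class = c("count_table", "data.frame"))
}

random_rna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "U"), n, TRUE, prob = prob), collapse = "")
}
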