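# Shared fixture builders. Everything is generated in code; no binary data.

write_toy_fasta <- function(lines, path = tempfile(fileext = ".fa")) {
  writeLines(lines, path)
  path
}

# A small gene-model GFF3-like file: list of rows
# (gene, scaffold, strand, exons = list(c(start, end), ...)), 1-based closed.
write_toy_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  rows <- unlist(lapply(genes, function(g) {
    vapply(g$exons, function(e) {
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id=%s",
              g$scaffold, e[1], e[2], g$strand, g$gene)
    }, "")
  }))
  writeLines(rows, path)
  path
}

# Brute-force K2P proportion counting over an explicit aligned pair,
# written independently of the package's counting code.
brute_pq <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  ts <- 0; tv <- 0; n <- 0
  for (i in seq_along(va)) {
    x <- va[i]; y <- vb[i]
    if (!(x %in% acgt) || !(y %in% acgt)) next
    n <- n + 1
    if (x == y) next
    pur <- c("A", "G")
    if ((x %in% pur) == (y %in% pur)) ts <- ts + 1 else tv <- tv + 1
  }
  list(P = ts / n, Q = tv / n, n = as.integer(n))
}

# Candidate row accessor: extract both LTR sequences of a simulated element.
ltr_seqs <- function(sim, i) {
  cd <- sim$candidates[i, ]
  seq <- sim$genome[[cd$scaffold_id]]$seq
  list(ltr5 = substr(seq, cd$ltr5_start, cd$ltr5_end),
       ltr3 = substr(seq, cd$ltr3_start, cd$ltr3_end))
}

# Run validate_element over all candidates of a simulation, returning the
# flags next to the truth table.
validate_all <- function(sim, cfg = run_config()) {
  flags <- t(vapply(seq_len(nrow(sim$candidates)), function(i) {
    ev <- validate_element(sim$genome, sim$candidates[i, ], config = cfg)
    c(ev$flags, pass = ev$overall_pass)
  }, c(termini = TRUE, tsd = TRUE, pbs = TRUE, ppt = TRUE, pass = TRUE)))
  cbind(sim$truth, as.data.frame(flags))
}
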