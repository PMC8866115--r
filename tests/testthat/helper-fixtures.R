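# Shared fixtures built in code.

random_cds <- function(n_codons, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1] <- "ATG"
  for (i in 2:(n_codons - 1)) {
    repeat {
      c3 <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!c3 %in% stops) break
    }
    codons[i] <- c3
  }
  codons[n_codons] <- sample(stops, 1)
  paste(codons, collapse = "")
}
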