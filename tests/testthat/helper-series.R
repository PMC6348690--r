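# random test instances and small simulation helpers shared across test files

random_pair <- function(n, dist = c("normal", "integer")) {
  dist <- match.arg(dist)
  if (dist == "normal") {
    list(x = rnorm(n), y = rnorm(n))
  } else {
    list(x = as.numeric(sample(-3:3, n, replace = TRUE)),
         y = as.numeric(sample(-3:3, n, replace = TRUE)))
  }
}

ar1_series <- function(rho, n, burn = 100) {
  e <- rnorm(burn + n)
  as.numeric(stats::filter(e, rho, method = "recursive", init = rnorm(1)))[(burn + 1):(burn + n)]
}

# small synthetic abundance tibble in read_abundance() layout
toy_table <- function(n_factor = 6, n_time = 30, seed = 42, missing = 0) {
  set.seed(seed)
  m <- t(replicate(n_factor, exp(ar1_series(0.4, n_time))))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  colnames(m) <- as.character(seq_len(n_time))
  dplyr::bind_cols(tibble::tibble(factor_id = paste0("OTU", seq_len(n_factor))),
                   tibble::as_tibble(m))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
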