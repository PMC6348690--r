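#' Read a factor-by-time abundance table
#'
#' Reads a TSV whose header row holds time labels and whose first column
#' holds factor (e.g. OTU) identifiers. Empty cells and `NA` tokens are
#' treated as missing. Ragged rows, duplicated factor identifiers, fewer
#' than three time points, and non-ascending numeric time labels are format
#' errors reported with line numbers.
#'
#' @param path Path to a tab-separated file.
#' @param na Tokens (besides the empty cell) read as missing.
#' @return A tibble whose first column is `factor_id` and whose remaining
#'   columns (one per time point, named by the time labels) are numeric.
#' @export
read_abundance <- function(path, na = c("", "NA")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 2) {
    abort("File must contain a header row and at least one factor row.",
          class = "deplsa_error_format")
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  time_labels <- header[-1]
  if (length(time_labels) < 3) {
    abort("Fewer than 3 time points (line 1).", class = "deplsa_error_format")
  }
  widths <- lengths(cells[-1])
  bad <- which(widths != length(header))
  if (length(bad)) {
    abort(sprintf("Ragged row(s) at line(s) %s: expected %d fields.",
                  paste(bad + 1L, collapse = ", "), length(header)),
          class = "deplsa_error_format")
  }
  ids <- vapply(cells[-1], `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("Duplicate factor ID(s): %s (lines %s).",
                  paste(dup, collapse = ", "),
                  paste(which(ids %in% dup) + 1L, collapse = ", ")),
          class = "deplsa_error_format")
  }
  num_t <- suppressWarnings(as.numeric(time_labels))
  if (!anyNA(num_t) && any(diff(num_t) <= 0)) {
    abort("Time labels must be strictly increasing (line 1).",
          class = "deplsa_error_format")
  }
  vals <- lapply(cells[-1], function(row) {
    v <- row[-1]
    v[v %in% na] <- NA
    suppressWarnings(as.numeric(v))
  })
  mat <- do.call(rbind, vals)
  colnames(mat) <- time_labels
  dplyr::bind_cols(tibble::tibble(factor_id = ids),
                   tibble::as_tibble(mat))
}

abundance_matrix <- function(table) {
  if (!is.data.frame(table) || names(table)[1] != "factor_id") {
    abort("`table` must be a tibble with a leading `factor_id` column (see read_abundance()).",
          class = "deplsa_error_input")
  }
  m <- as.matrix(table[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$factor_id
  m
}

#' Filter factors by prevalence
#'
#' Keeps factors observed — nonmissing *and* nonzero, since zeros in OTU
#' tables encode absence — in at least `min_fraction` of the time points
#' (inclusive threshold).
#'
#' @param table Abundance tibble from [read_abundance()].
#' @param min_fraction Required observed fraction, in (0, 1].
#' @return The filtered tibble (warning if no factor survives).
#' @export
prevalence_filter <- function(table, min_fraction) {
  m <- abundance_matrix(table)
  if (length(min_fraction) != 1 || is.na(min_fraction) || min_fraction <= 0 ||
      min_fraction > 1) {
    abort("`min_fraction` must lie in (0, 1].", class = "deplsa_error_param")
  }
  observed <- rowMeans(!is.na(m) & m != 0)
  keep <- observed >= min_fraction
  if (!any(keep)) warn("No factor passes the prevalence filter.")
  table[keep, , drop = FALSE]
}

#' Fill missing values by linear interpolation
#'
#' Interior gaps are interpolated linearly against the time index; leading
#' and trailing gaps are filled with the nearest observed value (constant
#' extension). Each row must have at least two observed points.
#'
#' @param table Abundance tibble from [read_abundance()].
#' @return The tibble with no missing values.
#' @export
interpolate_missing <- function(table) {
  m <- abundance_matrix(table)
  short <- rowSums(!is.na(m)) < 2
  if (any(short)) {
    abort(sprintf("Factor(s) with fewer than 2 observed points: %s.",
                  paste(rownames(m)[short], collapse = ", ")),
          class = "deplsa_error_input")
  }
  idx <- seq_len(ncol(m))
  filled <- t(apply(m, 1, function(row) {
    if (!anyNA(row)) return(row)
    approx(idx[!is.na(row)], row[!is.na(row)], xout = idx, rule = 2)$y
  }))
  out <- table
  out[, -1] <- as.data.frame(filled)
  out
}

#' Storey q-values (with Benjamini-Hochberg fallback)
#'
#' Estimates the null proportion `pi0` on the lambda grid,
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)`, smooths it with a cubic
#' smoothing spline (df = 3) and evaluates the smoother at the largest
#' lambda; q-values are the step-up transform
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. Storey's `pi0` can be
#' unstable for few tests, so `method = "bh"` (pi0 fixed at 1, i.e.
#' Benjamini-Hochberg) is available.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Grid for the `pi0` smoother.
#' @return Vector of q-values in input order.
#' @export
qvalue_adjust <- function(p, method = c("storey", "bh"),
                          lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].", class = "deplsa_error_input")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  pi0 <- if (method == "bh") 1 else estimate_pi0(p, lambda)
  ord <- order(p)
  q <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

estimate_pi0 <- function(p, lambda) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

#' All-pairs local similarity analysis of an abundance table
#'
#' Runs the chosen significance method on every unordered pair of factors in
#' a complete (filtered and interpolated) abundance table, then attaches
#' q-values for false discovery rate control. Series are standardized to
#' mean 0 and unit variance first by default, so scores are comparable
#' across pairs of factors measured on different scales. The reported delay
#' is `start_j - start_i`: positive means the first factor of the pair
#' leads. Pairs whose test fails are kept as NA rows (with a warning).
#'
#' @param table Abundance tibble ([read_abundance()]), no missing values.
#' @param method One of `"ddlsa"`, `"tlsa"`, `"lsares_ar"`, `"lsares_arma"`,
#'   `"permutation"`.
#' @param max_delay Maximum delay D (default 3, the usual choice for real
#'   abundance tables; the simulation studies use 0).
#' @param standardize Standardize each series first (default `TRUE`).
#' @param fdr_method Passed to [qvalue_adjust()].
#' @param n_perm,seed For `method = "permutation"`.
#' @return A tibble with one row per unordered factor pair: `factor_i`,
#'   `factor_j`, `method`, `score`, `delay`, `start_i`, `start_j`, `length`,
#'   `sign`, `statistic`, `p_value`, `q_value`.
#' @export
pairwise_analyze <- function(table,
                             method = c("ddlsa", "tlsa", "lsares_ar",
                                        "lsares_arma", "permutation"),
                             max_delay = 3, standardize = TRUE,
                             fdr_method = c("storey", "bh"), n_perm = 1000,
                             seed = NULL) {
  method <- match.arg(method)
  fdr_method <- match.arg(fdr_method)
  m <- abundance_matrix(table)
  if (anyNA(m)) {
    abort("Table contains missing values; run interpolate_missing() first.",
          class = "deplsa_error_input")
  }
  if (standardize) m <- t(apply(m, 1, standardize))
  ids <- rownames(m)
  pairs <- utils::combn(length(ids), 2)
  run_one <- function(i, j) {
    res <- tryCatch({
      t <- switch(method,
        ddlsa = ddlsa_test(m[i, ], m[j, ], max_delay),
        tlsa = tlsa_test(m[i, ], m[j, ], max_delay),
        lsares_ar = lsares_test(m[i, ], m[j, ], max_delay, family = "AR"),
        lsares_arma = lsares_test(m[i, ], m[j, ], max_delay, family = "ARMA"),
        permutation = permutation_test(m[i, ], m[j, ], max_delay,
                                       n_perm = n_perm))
      dplyr::rename(tidy(t), start_i = "start_x", start_j = "start_y")
    }, error = function(e) NULL)
    if (is.null(res)) {
      res <- tibble::tibble(method = method_labels[[method]], score = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            n = ncol(m), delay = NA_integer_,
                            start_i = NA_integer_, start_j = NA_integer_,
                            length = NA_integer_, sign = NA_integer_)
    }
    dplyr::bind_cols(tibble::tibble(factor_i = ids[i], factor_j = ids[j]), res)
  }
  out <- with_seed(seed, purrr::map2_dfr(pairs[1, ], pairs[2, ], run_one))
  n_fail <- sum(is.na(out$p_value))
  if (n_fail > 0) {
    warn(sprintf("%d pair(s) failed and are reported as NA rows.", n_fail))
  }
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$q_value[ok] <- qvalue_adjust(out$p_value[ok], fdr_method)
  dplyr::select(out, "factor_i", "factor_j", "method", "score", "delay",
                "start_i", "start_j", "length", "sign", "statistic",
                "p_value", "q_value")
}

#' Extract the significant pair set from a pairwise result
#'
#' @param results Tibble from [pairwise_analyze()].
#' @param p_cut,q_cut Significance thresholds on p- and q-values.
#' @return Character vector of canonical unordered pair keys.
#' @export
significant_pairs <- function(results, p_cut = 0.05, q_cut = 0.05) {
  sig <- !is.na(results$p_value) & results$p_value <= p_cut &
    !is.na(results$q_value) & results$q_value <= q_cut
  pair_key(results$factor_i[sig], results$factor_j[sig])
}

#' Sorensen similarity of two significant-association sets
#'
#' `2 |A intersect B| / (|A| + |B|)` for two sets of unordered factor pairs
#' (as returned by [significant_pairs()], or two-column data frames).
#' Defined as 0 (with a warning) when either set is empty.
#'
#' @param set_a,set_b Character vectors of pair keys or two-column data
#'   frames of factor pairs.
#' @return A number in `[0, 1]`.
#' @export
sorensen_index <- function(set_a, set_b) {
  canon <- function(s) {
    if (is.data.frame(s)) s <- pair_key(s[[1]], s[[2]])
    unique(s)
  }
  a <- canon(set_a)
  b <- canon(set_b)
  if (length(a) == 0 || length(b) == 0) {
    warn("Empty association set: Sorensen index defined as 0.")
    return(0)
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Overlap of significant associations across methods
#'
#' Thresholds each method's pairwise results at (`p <= p_cut`,
#' `q <= q_cut`) and reports, for every nonempty combination of methods, the
#' number of pairs significant in *all* of them (`n_intersection`) and in
#' exactly that combination and no other (`n_exclusive`, the Venn region).
#' All results must cover the same pair universe.
#'
#' @param results_by_method Named list of tibbles from [pairwise_analyze()].
#' @param p_cut,q_cut Significance thresholds.
#' @return A tibble with columns `methods`, `n_methods`, `n_intersection`,
#'   `n_exclusive`.
#' @export
method_overlap <- function(results_by_method, p_cut = 0.05, q_cut = 0.05) {
  if (!is.list(results_by_method) || length(results_by_method) < 1 ||
      is.null(names(results_by_method))) {
    abort("`results_by_method` must be a named list of pairwise results.",
          class = "deplsa_error_input")
  }
  universes <- lapply(results_by_method, function(r)
    sort(pair_key(r$factor_i, r$factor_j)))
  if (length(unique(universes)) != 1) {
    abort("All methods must be run on the same pair universe.",
          class = "deplsa_error_input")
  }
  sets <- lapply(results_by_method, significant_pairs, p_cut = p_cut,
                 q_cut = q_cut)
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  purrr::map_dfr(combos, function(cm) {
    inter <- Reduce(intersect, sets[cm])
    others <- setdiff(nm, cm)
    excl <- if (length(others)) setdiff(inter, unique(unlist(sets[others])))
            else inter
    tibble::tibble(methods = paste(cm, collapse = "+"),
                   n_methods = length(cm),
                   n_intersection = length(inter),
                   n_exclusive = length(excl))
  })
}
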