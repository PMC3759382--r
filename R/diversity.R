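# Positional diversity statistics: position frequency matrices, Shannon
# entropy, Weblogo-style information content (S_max - S_obs) and
# Kullback-Leibler divergence between selection rounds. All logarithms are
# base 2 (bits).

pfm_alphabet <- function(alphabet) {
  switch(alphabet,
    dna = DNA_BASES,
    protein = AA_ALPHABET,
    abort("alphabet must be 'dna' or 'protein'.")
  )
}

new_pfm <- function(freqs, alphabet, n_sequences, weighting) {
  symbols <- pfm_alphabet(alphabet)
  stopifnot(ncol(freqs) == length(symbols))
  colnames(freqs) <- symbols
  structure(
    freqs,
    alphabet = alphabet,
    n_sequences = n_sequences,
    weighting = weighting,
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf(
    "<pfm> %s, %d positions, weighting=%s, n=%s\n",
    attr(x, "alphabet"), nrow(x), attr(x, "weighting"),
    format(attr(x, "n_sequences"))
  ))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Build a position frequency matrix from fixed-length sequences
#'
#' @param sequences Character vector of equal-length sequences over the
#'   alphabet (27-nt HCDR3s or 9-residue peptides).
#' @param counts Optional integer weights per sequence (read counts); ignored
#'   under `weighting = "unique"`.
#' @param alphabet `"dna"` (4 symbols) or `"protein"` (20 symbols; the
#'   amber-suppressed TAG is already folded into Q by translation).
#' @param weighting `"unique"` (every distinct sequence weighs 1, the
#'   convention for diversity statistics, where sequences are not weighted by
#'   their frequency) or `"counts"` (read-count weighted).
#' @return A `pfm`: positions x symbols matrix of frequencies (rows sum to
#'   1), with attributes `alphabet`, `weighting`, `n_sequences`.
#' @examples
#' build_pfm(c("AAA", "AAC"), alphabet = "dna")
#' @export
build_pfm <- function(sequences, counts = NULL,
                      alphabet = c("dna", "protein"),
                      weighting = c("unique", "counts")) {
  alphabet <- match.arg(alphabet)
  weighting <- match.arg(weighting)
  if (length(sequences) == 0) abort("Cannot build a PFM from zero sequences.")
  len <- unique(nchar(sequences))
  if (length(len) != 1) abort("All sequences must have the same length.")
  symbols <- pfm_alphabet(alphabet)
  w <- if (weighting == "counts") {
    if (is.null(counts)) abort("weighting='counts' requires a counts vector.")
    as.numeric(counts)
  } else {
    rep(1, length(sequences))
  }
  if (weighting == "unique" && anyDuplicated(sequences)) {
    dup <- !duplicated(sequences)
    sequences <- sequences[dup]
    w <- w[dup]
  }
  chars <- matrix(
    unlist(strsplit(sequences, ""), use.names = FALSE),
    ncol = len, byrow = TRUE
  )
  bad <- setdiff(unique(as.vector(chars)), symbols)
  if (length(bad) > 0) {
    abort(paste0(
      "Sequence symbol(s) outside the ", alphabet, " alphabet: ",
      paste(bad, collapse = ", ")
    ))
  }
  freqs <- vapply(seq_len(len), function(i) {
    tot <- vapply(
      split(w, factor(chars[, i], levels = symbols)),
      sum, numeric(1)
    )
    tot / sum(w)
  }, numeric(length(symbols)))
  new_pfm(t(freqs),
    alphabet = alphabet,
    n_sequences = length(sequences), weighting = weighting
  )
}

#' Position frequency matrix of one counted pool
#'
#' Convenience wrapper building a [build_pfm()] matrix straight from a
#' `pool_counts` table, at either sequence level.
#'
#' @param counts A `pool_counts` tibble from [count_pools()].
#' @param pool One pool id.
#' @param level `"nt"` or `"peptide"`.
#' @param weighting `"unique"` (default) or `"counts"`.
#' @return A `pfm`.
#' @export
pool_pfm <- function(counts, pool, level = c("nt", "peptide"),
                     weighting = c("unique", "counts")) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  sel <- counts[counts$pool_id == pool, ]
  if (nrow(sel) == 0) abort(sprintf("Pool '%s' has no counted sequences.", pool))
  if (level == "nt") {
    build_pfm(sel$hcdr3_nt, counts = sel$n, alphabet = "dna", weighting = weighting)
  } else {
    pep <- sel |>
      group_by(.data$peptide) |>
      summarise(n = sum(.data$n), .groups = "drop")
    build_pfm(pep$peptide, counts = pep$n, alphabet = "protein", weighting = weighting)
  }
}

#' Shannon entropy of a discrete distribution
#'
#' `S = -sum(p * log(p))` with the convention `0 * log(0) = 0`.
#'
#' @param p Numeric vector of probabilities (must sum to 1).
#' @param base Logarithm base; 2 (bits) by default.
#' @return Entropy in `[0, log_base(length(p))]`.
#' @examples
#' shannon_entropy(rep(0.25, 4)) # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
shannon_entropy <- function(p, base = 2) {
  if (any(p < 0)) abort("Probabilities must be non-negative.")
  if (abs(sum(p) - 1) > 1e-6) abort("Probabilities must sum to 1.")
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Per-position entropy and information content of a PFM
#'
#' Information content at a position is `IC = S_max - S_obs`, with
#' `S_max = log2(k)` for a `k`-symbol alphabet (2 bits for DNA, log2(20) for
#' protein, taking every residue as equally likely a priori). This is the
#' sequence-logo letter-stack height. No small-sample correction is applied
#' by default.
#'
#' @param pfm A `pfm` from [build_pfm()] or [theoretical_pfm()].
#' @param small_sample_correction Subtract the Weblogo asymptotic bias term
#'   `(k - 1) / (2 ln(2) n)` from IC (needs a finite `n_sequences`).
#' @return An `entropy_profile` tibble: `position`, `entropy`, `ic` (bits),
#'   with attribute `s_max`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  k <- ncol(pfm)
  s_max <- log2(k)
  s_obs <- apply(unclass(pfm), 1, shannon_entropy)
  ic <- s_max - s_obs
  if (small_sample_correction) {
    n <- attr(pfm, "n_sequences")
    if (!is.finite(n)) abort("Small-sample correction needs a finite n_sequences.")
    ic <- pmax(ic - (k - 1) / (2 * log(2) * n), 0)
  }
  structure(
    tibble(position = seq_len(nrow(pfm)), entropy = s_obs, ic = ic),
    s_max = s_max,
    alphabet = attr(pfm, "alphabet"),
    class = c("entropy_profile", class(tibble()))
  )
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D(P || Q) = sum(P * log2(P / Q))`, with `0 * log(0/q) = 0`. Asymmetric
#' and non-negative; zero only when the distributions coincide.
#'
#' @param p,q Probability vectors of equal length, each summing to 1.
#' @param base Logarithm base (2 = bits).
#' @return A single non-negative number.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # 1 bit
#' @export
kl_divergence <- function(p, q, base = 2) {
  if (length(p) != length(q)) abort("p and q must have equal length.")
  if (any(p < 0) || any(q < 0)) abort("Probabilities must be non-negative.")
  nz <- p > 0
  if (any(q[nz] == 0)) {
    abort("Q is zero where P has mass; use a positive pseudocount.")
  }
  sum(p[nz] * log(p[nz] / q[nz], base = base))
}

#' Per-position Kullback-Leibler divergence between two PFMs
#'
#' `D(P || Q) = sum(P * log2(P / Q))` at every position, after smoothing both
#' distributions with a pseudocount (added to every symbol, then
#' renormalised). Conventionally P is the selected (round 3) profile and Q
#' the unselected (round 0) reference. D is non-negative and zero only when
#' the smoothed distributions coincide.
#'
#' @param pfm_p,pfm_q `pfm` objects with matching alphabet and length
#'   (observed and model distributions).
#' @param pseudocount Per-symbol pseudo-observations added to each position's
#'   symbol counts before renormalising (default 0.5); with the 10^4-10^5
#'   sequences of a typical pool the induced bias is negligible while removing
#'   zeros. With 0, a zero in Q where P has mass raises an error.
#' @return A `kl_profile` tibble: `position`, `kl` (bits).
#' @export
kl_profile <- function(pfm_p, pfm_q, pseudocount = 0.5) {
  stopifnot(inherits(pfm_p, "pfm"), inherits(pfm_q, "pfm"))
  if (!identical(attr(pfm_p, "alphabet"), attr(pfm_q, "alphabet")) ||
    nrow(pfm_p) != nrow(pfm_q)) {
    abort("PFMs must share alphabet and length.")
  }
  if (pseudocount < 0) abort("pseudocount must be >= 0.")
  k <- ncol(pfm_p)
  smooth <- function(m) {
    if (pseudocount == 0) return(unclass(m))
    n <- attr(m, "n_sequences")
    if (!is.finite(n)) {
      abort("A positive pseudocount needs a PFM with finite n_sequences; use pseudocount = 0 for theoretical profiles.")
    }
    cnt <- unclass(m) * n + pseudocount
    cnt / rowSums(cnt)
  }
  p <- smooth(pfm_p)
  q <- smooth(pfm_q)
  kl <- vapply(seq_len(nrow(p)), function(i) {
    kl_divergence(p[i, ], q[i, ])
  }, numeric(1))
  structure(
    tibble(position = seq_len(nrow(p)), kl = kl),
    pseudocount = pseudocount,
    weighting = attr(pfm_p, "weighting"),
    class = c("kl_profile", class(tibble()))
  )
}

#' @exportS3Method generics::tidy
tidy.pfm <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "freq")) |>
    mutate(position = as.integer(.data$Var1), symbol = as.character(.data$Var2)) |>
    select("position", "symbol", "freq")
}

#' @exportS3Method generics::glance
glance.entropy_profile <- function(x, ...) {
  tibble(
    n_positions = nrow(x),
    s_max = attr(x, "s_max"),
    mean_entropy = mean(x$entropy),
    total_ic = sum(x$ic)
  )
}

#' @exportS3Method generics::glance
glance.kl_profile <- function(x, ...) {
  tibble(n_positions = nrow(x), total_kl = sum(x$kl), max_kl = max(x$kl))
}

#' Plot a per-position information-content profile
#'
#' @param object An `entropy_profile`.
#' @param ... Unused.
#' @return A ggplot object (bar chart of IC in bits by position).
#' @exportS3Method ggplot2::autoplot
autoplot.entropy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Position", y = "Information content (bits)",
      title = "Positional information content (S_max - S_obs)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-position Kullback-Leibler divergence profile
#'
#' @param object A `kl_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kl_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$kl)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "Position", y = "KL divergence (bits)",
      title = "Entropy change from round 0 to round 3 by position"
    ) +
    ggplot2::theme_minimal()
}
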