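
# ---- Genetic code and codon state space -------------------------------------
#
# The codon substitution machinery works on the 61 sense codons of the
# universal genetic code; stop codons (TAA, TAG, TGA) are excluded from the
# state space, following standard codon-model practice.

.codon_env <- new.env(parent = emptyenv())

#' Sense-codon table for the universal genetic code
#'
#' Returns the internal lookup used by all codon-model code: the 61 sense
#' codons, their amino-acid translations, and the classification of every
#' single-nucleotide codon pair as transition/transversion and
#' synonymous/nonsynonymous.
#'
#' @return A list with elements `codons` (character 61), `aa` (character 61),
#'   and `pairs`, a data frame of single-nucleotide-difference codon pairs
#'   with columns `i`, `j`, `transition` and `synonymous`.
#' @export
codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  nt <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nt, nt, nt, stringsAsFactors = FALSE)[, 3:1], 1L,
                 paste0, collapse = "")
  aa64 <- vapply(all64, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  stopifnot(length(sense) == 61L)
  spl <- strsplit(sense, "")
  m <- do.call(rbind, spl)
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  ii <- jj <- integer(0); tr <- sy <- logical(0)
  for (i in 1:60) {
    for (j in (i + 1):61) {
      diffs <- which(m[i, ] != m[j, ])
      if (length(diffs) == 1L) {
        ii <- c(ii, i); jj <- c(jj, j)
        tr <- c(tr, is_transition(m[i, diffs], m[j, diffs]))
        sy <- c(sy, aa[i] == aa[j])
      }
    }
  }
  tab <- list(
    codons = sense, aa = unname(aa),
    pairs = data.frame(i = ii, j = jj, transition = tr, synonymous = sy)
  )
  .codon_env$tab <- tab
  tab
}

#' Build a Goldman-Yang codon rate matrix
#'
#' Constructs the 61 x 61 generator of the GY94-style codon substitution
#' process: zero for multi-nucleotide changes, and proportional to
#' `pi[j]`, `kappa * pi[j]`, `omega * pi[j]` or `omega * kappa * pi[j]` for
#' synonymous transversions/transitions and nonsynonymous
#' transversions/transitions respectively. By default the matrix is scaled so
#' the expected number of substitutions per codon site is 1 at stationarity.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Codon stationary frequencies (length 61, non-negative, sum 1).
#'   Defaults to uniform.
#' @param scale If `TRUE` (default), rescale to unit mean rate.
#' @return A 61 x 61 matrix with zero row sums.
#' @export
build_codon_rate_matrix <- function(kappa, omega, pi = NULL, scale = TRUE) {
  tab <- codon_table()
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  if (length(pi) != 61L || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("`pi` must be 61 non-negative frequencies summing to 1", call. = FALSE)
  }
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  if (omega < 0) stop("`omega` must be non-negative", call. = FALSE)
  Q <- matrix(0, 61, 61)
  p <- tab$pairs
  rate <- ifelse(p$transition, kappa, 1) * ifelse(p$synonymous, 1, omega)
  Q[cbind(p$i, p$j)] <- rate * pi[p$j]
  Q[cbind(p$j, p$i)] <- rate * pi[p$i]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# mean substitution rate of the *unscaled* GY matrix at (kappa, omega, pi)
codon_mean_rate <- function(kappa, omega, pi = NULL) {
  Q <- build_codon_rate_matrix(kappa, omega, pi, scale = FALSE)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  -sum(pi * diag(Q))
}

# Spectral decomposition of a reversible codon generator, for fast P(t).
# Returns U1, U2, lambda with P(t) = U1 %*% (exp(lambda * t) * U2).
codon_decompose <- function(kappa, omega, pi = NULL, rate_scale = 1) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  Q <- build_codon_rate_matrix(kappa, omega, pi, scale = FALSE) / rate_scale
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))   # D^1/2 Q D^-1/2, symmetric for reversible Q
  B <- (B + t(B)) / 2          # symmetrize against roundoff
  e <- eigen(B, symmetric = TRUE)
  list(
    U1 = e$vectors / sq,       # D^-1/2 U  (column-wise: rows scaled)
    U2 = t(e$vectors) * rep(sq, each = 61),  # t(U) D^1/2
    lambda = e$values
  )
}

codon_pmat <- function(dec, t) {
  P <- dec$U1 %*% (exp(dec$lambda * t) * dec$U2)
  P[P < 0] <- 0
  P
}

#' F3x4 codon frequencies from an alignment
#'
#' Estimates codon stationary frequencies as the product of the empirical
#' nucleotide frequencies at each codon position, with stop codons removed
#' and the remainder renormalized (the `codeml` F3x4 convention).
#'
#' @param alignment Named character vector of in-frame nucleotide sequences.
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies_f3x4 <- function(alignment) {
  tab <- codon_table()
  nt <- c("T", "C", "A", "G")
  chars <- strsplit(toupper(paste(alignment, collapse = "")), "")[[1]]
  n <- length(chars)
  if (n %% 3L != 0L) stop("alignment length not divisible by 3", call. = FALSE)
  pos <- rep_len(1:3, n)
  freq <- matrix(0, 3, 4, dimnames = list(NULL, nt))
  for (k in 1:3) {
    tb <- table(factor(chars[pos == k], levels = nt))
    freq[k, ] <- as.numeric(tb)
  }
  if (any(rowSums(freq) == 0)) return(rep(1 / 61, 61))
  freq <- freq / rowSums(freq)
  cd <- strsplit(tab$codons, "")
  pi <- vapply(cd, function(x) freq[1, x[1]] * freq[2, x[2]] * freq[3, x[3]], numeric(1))
  if (sum(pi) <= 0) return(rep(1 / 61, 61))
  pi / sum(pi)
}

# ---- Alignment encoding -----------------------------------------------------

# Encode a named character vector of in-frame sequences as an integer matrix
# (taxa x codon sites) of sense-codon indices; gaps/ambiguities become NA.
# Internal stop codons are an error per the alignment invariant.
codon_index_matrix <- function(alignment) {
  tab <- codon_table()
  if (is.null(names(alignment)) || any(names(alignment) == "")) {
    stop("alignment sequences must be named", call. = FALSE)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("sequences have unequal lengths", call. = FALSE)
  if (lens[1] %% 3L != 0L) {
    stop("alignment length not divisible by 3 (out-of-frame)", call. = FALSE)
  }
  nsite <- lens[1] / 3L
  stops <- c("TAA", "TAG", "TGA")
  out <- matrix(NA_integer_, length(alignment), nsite,
                dimnames = list(names(alignment), NULL))
  for (s in seq_along(alignment)) {
    cods <- substring(toupper(alignment[[s]]), 3L * seq_len(nsite) - 2L, 3L * seq_len(nsite))
    bad <- cods %in% stops
    if (any(bad)) {
      stop(sprintf("internal stop codon in sequence '%s' at codon %d",
                   names(alignment)[s], which(bad)[1]), call. = FALSE)
    }
    out[s, ] <- match(cods, tab$codons)   # non-ACGT codons -> NA (missing)
  }
  out
}

# Collapse identical site columns; returns list(idx = taxa x npat, wt = counts)
compress_patterns <- function(ai) {
  key <- apply(ai, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(idx = ai[, u, drop = FALSE], wt = as.numeric(table(key)[key[u]]))
}
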