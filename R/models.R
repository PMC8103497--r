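# Substitution models: empirical amino-acid matrices (PAML dat layout),
# nucleotide GTR, discrete-gamma rates, generator and transition matrices.

#' Construct a substitution model
#'
#' A reversible substitution model is defined by a symmetric exchangeability
#' matrix `S` (zero diagonal), stationary frequencies `pi`, and a
#' discrete-gamma model of among-site rate variation with shape `alpha` and
#' `K` equal-probability categories.
#'
#' @param name Model label.
#' @param S Symmetric c x c exchangeability matrix, zero diagonal.
#' @param pi Stationary frequencies (positive, summing to 1 within 1e-8).
#' @param alpha Gamma shape (> 0); `Inf` means rate homogeneity.
#' @param K Number of rate categories (>= 1; 1 also means homogeneity).
#' @param plus_F Whether `pi` are empirical (data-derived) frequencies.
#' @param alphabet `"AA20"` or `"NT4"`.
#' @return An object of class `teleo_model`.
#' @export
teleo_model <- function(name, S, pi, alpha = 1, K = 4L, plus_F = FALSE,
                        alphabet = c("AA20", "NT4")) {
  alphabet <- match.arg(alphabet)
  c <- length(.alphabets[[alphabet]]$states)
  stopifnot(is.matrix(S), nrow(S) == c, ncol(S) == c)
  if (max(abs(S - t(S))) > 1e-10) stop("S must be symmetric", call. = FALSE)
  if (any(pi <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-8)
    stop("frequencies must sum to 1 (got ", format(sum(pi)), ")",
         call. = FALSE)
  pi <- pi / sum(pi)
  if (!is.infinite(alpha) && alpha <= 0)
    stop("alpha must be > 0", call. = FALSE)
  stopifnot(K >= 1L)
  diag(S) <- 0
  structure(list(name = name, S = S, pi = as.numeric(pi), alpha = alpha,
                 K = as.integer(K), plus_F = plus_F, alphabet = alphabet),
            class = "teleo_model")
}

#' @export
print.teleo_model <- function(x, ...) {
  cat("<teleo_model> ", x$name, if (x$plus_F) "+F", "+G(alpha=",
      format(x$alpha, digits = 4), ", K=", x$K, ") [", x$alphabet, "]\n",
      sep = "")
  invisible(x)
}

.read_paml_dat <- function(path, c = 20L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- scan(text = paste(lines, collapse = "\n"), what = numeric(),
               quiet = TRUE)
  ntri <- c * (c - 1L) / 2L
  if (length(vals) < ntri + c)
    stop("malformed dat file: ", path, call. = FALSE)
  S <- matrix(0, c, c)
  k <- 1L
  for (i in 2:c) for (j in 1:(i - 1L)) {
    S[i, j] <- vals[k]; k <- k + 1L
  }
  S <- S + t(S)
  list(S = S, pi = vals[ntri + seq_len(c)])
}

#' Load an empirical substitution model
#'
#' The amino-acid models JTT, LG, Dayhoff, WAG and MTMAM are read from the
#' published exchangeability/frequency tables shipped with the package in
#' PAML dat layout. Supplying `freqs` replaces the model's default
#' frequencies with empirical ones (the +F variant). `"GTR"` returns a
#' 4-state nucleotide general time-reversible model with generic default
#' exchangeabilities (transitions four times transversions) and equal base
#' frequencies; its exchangeabilities are meant to be replaced by data
#' (see [fit_gtr()]).
#'
#' @param name One of `"JTT"`, `"LG"`, `"Dayhoff"`, `"WAG"`, `"MTMAM"`,
#'   `"GTR"` (case-insensitive).
#' @param freqs Optional empirical frequencies (positive, sum 1 within 1e-8);
#'   sets `plus_F`.
#' @param alpha,K Discrete-gamma shape and number of categories.
#' @return A [teleo_model].
#' @examples
#' m <- load_empirical_model("JTT", alpha = 0.7)
#' sum(m$pi)
#' @export
load_empirical_model <- function(name, freqs = NULL, alpha = 1, K = 4L) {
  key <- toupper(name)
  aa_files <- c(JTT = "jtt.dat", LG = "lg.dat", DAYHOFF = "dayhoff.dat",
                WAG = "wag.dat", MTMAM = "mtmam.dat")
  if (key %in% names(aa_files)) {
    path <- system.file("extdata", aa_files[[key]], package = "teleobase",
                        mustWork = TRUE)
    dat <- .read_paml_dat(path, 20L)
    S <- dat$S; pi <- dat$pi; alphabet <- "AA20"
  } else if (key == "GTR") {
    S <- matrix(0, 4, 4)
    # order A C G T; AC AG AT CG CT GT
    S[lower.tri(S)] <- c(1, 4, 1, 1, 4, 1)
    S <- S + t(S)
    pi <- rep(0.25, 4)
    alphabet <- "NT4"
  } else {
    stop("unknown model: '", name, "'", call. = FALSE)
  }
  plus_F <- !is.null(freqs)
  if (plus_F) {
    if (length(freqs) != length(pi) || any(freqs <= 0) ||
        abs(sum(freqs) - 1) > 1e-8)
      stop("malformed empirical frequencies", call. = FALSE)
    pi <- freqs / sum(freqs)
  }
  nm <- if (key == "DAYHOFF") "Dayhoff" else key
  teleo_model(nm, S, pi, alpha = alpha, K = K, plus_F = plus_F,
              alphabet = alphabet)
}

#' Build a grid of candidate models
#'
#' Expands model names by the +F flag, e.g. the standard amino-acid grid
#' \{JTT, LG, Dayhoff, WAG, MTMAM\} x \{-F, +F\}. Empirical frequencies are
#' filled in at fit time from the alignment being scored.
#'
#' @param names Character vector of model names.
#' @param plus_F Logical vector of +F settings to cross with `names`.
#' @param alpha,K Passed to [load_empirical_model()].
#' @return A named list of [teleo_model] objects; +F entries carry the flag
#'   but keep default frequencies until fitted.
#' @export
model_grid <- function(names = c("JTT", "LG", "Dayhoff", "WAG", "MTMAM"),
                       plus_F = c(FALSE, TRUE), alpha = 1, K = 4L) {
  out <- list()
  for (nm in names) for (pf in plus_F) {
    m <- load_empirical_model(nm, alpha = alpha, K = K)
    m$plus_F <- pf
    out[[paste0(m$name, if (pf) "+F", "+G")]] <- m
  }
  out
}

#' Discrete-gamma rate categories
#'
#' `K` equal-probability categories whose rates are the conditional means of
#' the gamma(shape = `alpha`, mean 1) density over its quantile bands, so
#' the mean rate is exactly 1.
#'
#' @param alpha Gamma shape (> 0). `Inf` gives a single unit rate.
#' @param K Number of categories (>= 1).
#' @return Numeric vector of `K` rates with mean 1.
#' @examples
#' mean(discrete_gamma(0.5, 4))  # exactly 1
#' @export
discrete_gamma <- function(alpha, K = 4L) {
  if (is.infinite(alpha)) return(rep(1, K))
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K == 1L) return(1)
  q <- qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  # E[X | band] * K for X ~ Gamma(alpha, alpha):
  # integral of x f(x) over band equals F_{alpha+1,alpha}(upper) - (lower)
  r <- (pgamma(bounds[-1L], shape = alpha + 1, rate = alpha) -
          pgamma(bounds[-(K + 1L)], shape = alpha + 1, rate = alpha)) * K
  r / mean(r)
}

#' Rate generator of a reversible model
#'
#' `Q[i, j] = S[i, j] * pi[j]` off the diagonal, rows summing to zero,
#' rescaled so the expected substitution rate at stationarity is 1
#' (`-sum(pi * diag(Q)) == 1`), which makes branch lengths expected
#' substitutions per site.
#'
#' @param m A [teleo_model] (or a list with `S` and `pi`).
#' @return The c x c generator matrix.
#' @export
build_generator <- function(m) {
  Q <- m$S * rep(m$pi, each = nrow(m$S))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(m$pi * diag(Q))
  if (mu <= 0) stop("degenerate generator", call. = FALSE)
  Q / mu
}

# symmetric eigendecomposition of the generator; P(t, r) = A exp(eva t r) B
.model_eigen <- function(m) {
  Q <- build_generator(m)
  sp <- sqrt(m$pi)
  Bsym <- Q * (sp %o% (1 / sp))
  Bsym <- (Bsym + t(Bsym)) / 2
  e <- eigen(Bsym, symmetric = TRUE)
  list(A = e$vectors / sp, B = t(e$vectors) * rep(sp, each = nrow(Q)),
       values = e$values, pi = m$pi)
}

#' Transition probability matrix
#'
#' `P = exp(Q * t * rate)` computed through the symmetric similarity
#' transform of the reversible generator.
#'
#' @param m A [teleo_model].
#' @param t Branch length (>= 0, expected substitutions/site).
#' @param rate Rate multiplier (>= 0), e.g. a gamma category rate.
#' @return Stochastic c x c matrix with stationary distribution `m$pi`.
#' @export
transition_matrix <- function(m, t, rate = 1) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  ed <- .model_eigen(m)
  P <- ed$A %*% (exp(ed$values * t * rate) * ed$B)
  P[P < 0] <- 0
  dimnames(P) <- list(.alphabets[[m$alphabet]]$states,
                      .alphabets[[m$alphabet]]$states)
  P
}
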