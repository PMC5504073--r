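## ZOOPS EM internals -------------------------------------------------------

## per-column natural-log lookup matrices (5 x w; N row NA) for a PWM and its
## reverse complement
pwm_log_lookup <- function(probs) {
  rbind(log(probs), rep(NA_real_, ncol(probs)))
}

## enumerate all w-mers of the training set and return the n_starts words
## most over-represented relative to the background (ranked by count, ties by
## count / background probability). Near-identical planted sites keep an
## intact consensus word in a large minority of copies, so the planted word
## dominates this ranking.
seed_words <- function(seqs, w, bg, n_starts) {
  words <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(character(0))
    substring(s, seq_len(L - w + 1L), seq_len(L - w + 1L) + w - 1L)
  }))
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (length(words) == 0L) stop("no N-free windows to seed motif discovery")
  tab <- table(words)
  tab <- sort(tab, decreasing = TRUE)
  cand <- head(tab, max(200L, n_starts * 10L))
  cc <- encode_dna(names(cand))
  bg_lp <- vapply(cc, function(code) {
    sum(window_bg_logprob(code, length(code), bg))
  }, numeric(1))
  o <- order(-as.integer(cand), bg_lp)
  names(cand)[o][seq_len(min(n_starts, length(cand)))]
}

#' De novo motif discovery by ZOOPS expectation-maximisation
#'
#' Discovers a single ungapped motif of fixed width in a set of sequences
#' under the ZOOPS model (each sequence carries zero or one occurrence),
#' against a Markov background — the model family behind classical
#' peak-motif discovery. The E-step computes the posterior over occurrence
#' positions (both strands by default) versus the background; the M-step
#' re-estimates the PWM from expected base counts plus pseudocount and the
#' per-sequence occurrence prior. Restarts are seeded from the most
#' over-represented width-w words; each restart runs a few burn-in
#' iterations, the best by likelihood is run to convergence. The
#' log-likelihood is non-decreasing across iterations by construction and is
#' checked at every step.
#'
#' @param seqs Character vector or `DNAStringSet` (e.g. peak-summit windows).
#' @param width Motif width in bp (>= 4).
#' @param background A `"markov_bg"` from [train_markov_background()].
#' @param n_starts Number of seeded restarts (default 5).
#' @param seed Integer seed governing any random tie-breaks.
#' @param model Occurrence model; only `"ZOOPS"` is implemented.
#' @param pseudo Pseudocount for the PWM M-step (default 0.01).
#' @param both_strands Scan both strands in the E-step (default TRUE; set
#'   FALSE for pre-oriented windows such as upstream extensions).
#' @param max_iter,tol Convergence controls on the log-likelihood.
#' @param null_check Calibrate against overfitting (default TRUE): the same
#'   EM is run on per-sequence shuffled copies of the input, and when the
#'   real fit's log-likelihood gain over the background-only model does not
#'   clearly exceed the shuffled fit's (factor 2), the discovery reports no
#'   motif — the returned PWM is flat at the background composition and
#'   `significant` is `FALSE`. ZOOPS EM always sharpens somewhat on pure
#'   background; this control is what distinguishes a real motif from that
#'   artefact.
#' @param burnin Iterations run per restart before selecting the best.
#' @return List of class `"zoops_em"`: `pwm` (the [new_pwm()] result),
#'   `loglik`, `ll_trace`, `gamma` (occurrence prior), `posterior`
#'   (per-sequence occurrence probability), `n_iter`, `seed_word`.
#' @export
em_discover <- function(seqs, width, background, n_starts = 5L, seed = 1L,
                        model = "ZOOPS", pseudo = 0.01, both_strands = TRUE,
                        max_iter = 100L, tol = 1e-4, burnin = 5L,
                        null_check = TRUE) {
  stopifnot(model == "ZOOPS")
  if (width < 4L) stop("motif width must be >= 4")
  seqs <- as.character(seqs)
  if (any(nchar(seqs) < width))
    stop("motif width exceeds the shortest sequence")
  set.seed(as.integer(seed))
  w <- as.integer(width)
  codes <- encode_dna(seqs)
  cc <- concat_codes(codes, sep = w)
  n <- length(seqs)
  P_all <- length(cc$codes) - w + 1L
  win_seq <- rep(NA_integer_, P_all)      # owning sequence of each window
  for (i in seq_len(n)) {
    Pi <- cc$lens[i] - w + 1L
    if (Pi >= 1L) win_seq[cc$offsets[i] + seq_len(Pi)] <- i
  }
  keep <- !is.na(win_seq)
  bgw <- window_bg_logprob(cc$codes, w, background)
  valid_mask <- !is.na(window_sums(cc$codes, pwm_log_lookup(
    matrix(0.25, 4L, w))))             # windows free of N and boundaries
  keep <- keep & valid_mask
  win_idx <- which(keep)                  # positions in the concatenation
  win_seq <- win_seq[keep]
  bgw <- bgw[keep]
  Pn <- tabulate(win_seq, nbins = n)      # valid windows per sequence
  if (all(Pn == 0L)) stop("no N-free windows of the requested width")
  n_str <- if (both_strands) 2L else 1L
  group_sum <- function(x) {              # per-sequence sums, length n
    out <- numeric(n)
    s <- rowsum(x, win_seq)
    out[as.integer(rownames(s))] <- s[, 1L]
    out
  }

  run_em <- function(pwm0, iters, ll_stop) {
    probs <- pwm0
    gamma <- 0.5
    ll_trace <- numeric(0)
    for (it in seq_len(iters)) {
      lookf <- pwm_log_lookup(probs)
      lf <- window_sums(cc$codes, lookf)[win_idx] - bgw
      if (both_strands) {
        lookr <- pwm_log_lookup(probs[4:1, w:1, drop = FALSE])
        lr <- window_sums(cc$codes, lookr)[win_idx] - bgw
      }
      prior <- gamma / (n_str * Pn[win_seq])
      ef <- prior * exp(pmin(lf, 500))
      er <- if (both_strands) prior * exp(pmin(lr, 500)) else NULL
      tot <- group_sum(ef + (if (both_strands) er else 0))
      denom <- (1 - gamma) + tot
      ll <- sum(log(denom))
      ll_trace <- c(ll_trace, ll)
      zf <- ef / denom[win_seq]
      zr <- if (both_strands) er / denom[win_seq] else NULL
      ## M-step
      cnt <- matrix(0, 4L, w)
      pos <- win_idx
      for (j in seq_len(w)) {
        bf <- cc$codes[pos + j - 1L]
        cnt[, j] <- cnt[, j] + rowsum_by_base(zf, bf)
        if (both_strands) {
          br <- 5L - cc$codes[pos + (w - j)]
          cnt[, j] <- cnt[, j] + rowsum_by_base(zr, br)
        }
      }
      cnt <- cnt + pseudo
      probs <- sweep(cnt, 2L, colSums(cnt), "/")
      q <- group_sum(zf + (if (both_strands) zr else 0))
      gamma <- min(max(mean(q), 1e-6), 1 - 1e-6)
      if (it > 1L && ll_stop &&
          ll_trace[it] - ll_trace[it - 1L] < tol) break
    }
    list(probs = probs, gamma = gamma, ll = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, posterior = q)
  }

  words <- seed_words(seqs, w, background, n_starts)
  fits <- lapply(words, function(wd)
    run_em(pwm_from_consensus(wd, 0.7)$probs, burnin, ll_stop = FALSE))
  best <- which.max(vapply(fits, `[[`, numeric(1), "ll"))
  final <- run_em(fits[[best]]$probs, max_iter, ll_stop = TRUE)
  dll <- diff(final$ll_trace)
  if (any(dll < -1e-6 * pmax(abs(final$ll_trace[-1]), 1)))
    warning("EM log-likelihood decreased; convergence is suspect")
  significant <- TRUE
  pwm <- new_pwm(final$probs, pseudo = pseudo)
  if (null_check) {
    ## the background-only model has log-likelihood 0 on this scale, so
    ## final$ll is the gain; compare it with the gain EM extracts from
    ## shuffled copies of the same sequences (pure overfitting)
    shuf <- vapply(seqs, function(s)
      paste(sample(strsplit(s, "")[[1L]]), collapse = ""), "",
      USE.NAMES = FALSE)
    null_fit <- em_discover(shuf, width, background, n_starts = n_starts,
                            seed = seed + 1L, pseudo = pseudo,
                            both_strands = both_strands,
                            max_iter = max_iter, tol = tol, burnin = burnin,
                            null_check = FALSE)
    if (final$ll < 2 * max(null_fit$loglik, 1e-6)) {
      significant <- FALSE
      flat <- matrix(background$p0, 4L, w,
                     dimnames = list(BASES, NULL))
      pwm <- new_pwm(flat, pseudo = pseudo)
    }
  }
  structure(list(pwm = pwm,
                 loglik = final$ll, ll_trace = final$ll_trace,
                 gamma = final$gamma, posterior = final$posterior,
                 n_iter = length(final$ll_trace),
                 significant = significant,
                 seed_word = words[best]),
            class = "zoops_em")
}

rowsum_by_base <- function(z, base) {
  out <- numeric(4L)
  s <- rowsum(z, factor(base, levels = 1:4))
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' @export
print.zoops_em <- function(x, ...) {
  cat("ZOOPS EM fit: consensus", x$pwm$consensus,
      sprintf(" logLik %.1f  gamma %.2f  (%d iterations)\n",
              x$loglik, x$gamma, x$n_iter))
  invisible(x)
}
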