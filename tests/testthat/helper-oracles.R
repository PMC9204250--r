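# Independent reference implementations used as oracles. These deliberately
# use naive loops / enumeration, not the package's code paths.

# naive stage-sum log-likelihood of a sequence: double loop over subjects and
# stages, masked features dropped
naive_sequence_ll <- function(p_event, p_noevent, ord, mask = NULL) {
  n <- nrow(p_event)
  total <- 0
  for (j in seq_len(n)) {
    pe <- p_event[j, ord]
    pn <- p_noevent[j, ord]
    if (!is.null(mask)) {
      keep <- !mask[j, ord]
      pe <- pe[keep]
      pn <- pn[keep]
    }
    kj <- length(pe)
    if (kj == 0) next
    s <- 0
    for (k in 0:kj) {
      term <- 1
      for (i in seq_len(kj)) term <- term * if (i <= k) pe[i] else pn[i]
      s <- s + term
    }
    total <- total + log(s / (kj + 1))
  }
  total
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# exact sequence posterior by enumeration of all K! orderings
exact_sequence_posterior <- function(p_event, p_noevent) {
  perms <- all_permutations(ncol(p_event))
  ll <- vapply(perms, function(p) naive_sequence_ll(p_event, p_noevent, p),
               numeric(1))
  w <- exp(ll - max(ll))
  list(perms = perms, prob = w / sum(w))
}

# pool-adjacent-violators for a (weighted) non-decreasing least-squares fit
pava <- function(y, w = rep(1, length(y))) {
  val <- as.numeric(y)
  wt <- as.numeric(w)
  len <- rep(1L, length(y))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-15) {
      merged <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / (wt[i] + wt[i + 1])
      val[i] <- merged
      wt[i] <- wt[i] + wt[i + 1]
      len[i] <- len[i] + len[i + 1]
      val <- val[-(i + 1)]
      wt <- wt[-(i + 1)]
      len <- len[-(i + 1)]
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep(val, len)
}

# Cox partial log-likelihood for one binary covariate, no ties in event times
cox_partial_ll <- function(beta, time, event, x) {
  ll <- 0
  for (j in which(event == 1)) {
    risk <- time >= time[j]
    ll <- ll + beta * x[j] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# single-kernel Gaussian event model built by hand (already monotone)
toy_kernel_model <- function(center_noevent, center_event, bw, w = 0.5,
                             direction = +1, feature = "toy") {
  m <- structure(
    list(feature = feature,
         centers = c(center_noevent, center_event),
         bandwidth_normal = bw, bandwidth_abnormal = bw,
         weights_abnormal = c(0, 1),
         weights_normal = c(1, 0),
         mixture_weight = w,
         disease_direction = as.integer(direction),
         n_iter = 0L, grid = NULL, posterior_grid = NULL,
         monotone_raw = NA),
    class = "kde_event_model")
  enforce_direction(m)
}

# ebm_likelihood built directly from matrices
manual_likelihood <- function(p_event, p_noevent, mask = NULL) {
  k <- ncol(p_event)
  feats <- sprintf("f%02d", seq_len(k))
  colnames(p_event) <- colnames(p_noevent) <- feats
  if (is.null(mask)) mask <- matrix(FALSE, nrow(p_event), k)
  colnames(mask) <- feats
  structure(
    list(p_event = p_event, p_noevent = p_noevent, mask = mask,
         subject_id = as.character(seq_len(nrow(p_event))), features = feats),
    class = "ebm_likelihood")
}
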