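# independent permutation-form Shapley oracle: average marginal contribution
# of each feature over all |F|! orderings (used against the subset-sum path)
permutation_shapley <- function(predict_fun, background, x) {
  background <- as.matrix(as.data.frame(background))
  p <- ncol(background)
  vfun <- function(S) {
    hyb <- background
    for (i in S) hyb[, i] <- x[[i]]
    mean(predict_fun(as.data.frame(hyb)))
  }
  perms <- all_permutations(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    S <- integer(0)
    for (i in perms[r, ]) {
      phi[i] <- phi[i] + vfun(c(S, i)) - vfun(S)
      S <- c(S, i)
    }
  }
  stats::setNames(phi / nrow(perms), colnames(background))
}

all_permutations <- function(p) {
  if (p == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(p - 1L)
  out <- NULL
  for (i in seq_len(p)) {
    rest <- setdiff(seq_len(p), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
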