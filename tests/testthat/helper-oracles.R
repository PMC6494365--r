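# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive results with naive scalar code so they stay
# independent of the vectorized / compiled implementation paths.

# scalar double-loop Gower oracle: plain per-pair, per-feature arithmetic
gower_oracle <- function(table, ranges = NULL) {
  feats <- table$schema$features
  n <- length(table$patient_ids)
  if (is.null(ranges)) {
    ranges <- list()
    for (j in seq_len(nrow(feats))) {
      if (feats$kind[j] != "continuous") next
      x <- table$data[[feats$name[j]]]
      x <- x[!is.na(x)]
      ranges[[feats$name[j]]] <- if (length(x)) max(x) - min(x) else 0
    }
  }
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      num <- 0; den <- 0
      for (j in seq_len(nrow(feats))) {
        xa <- table$data[[feats$name[j]]][a]
        xb <- table$data[[feats$name[j]]][b]
        if (is.na(xa) || is.na(xb)) next
        w <- feats$weight[j]
        s <- if (feats$kind[j] == "continuous") {
          r <- ranges[[feats$name[j]]]
          if (r > 0) abs(xa - xb) / r else 0
        } else {
          if (identical(as.character(xa), as.character(xb))) 0 else 1
        }
        num <- num + w * s
        den <- den + w
      }
      if (den == 0) stop("oracle: undefined pair")
      D[a, b] <- D[b, a] <- num / den
    }
  }
  dimnames(D) <- list(table$patient_ids, table$patient_ids)
  D
}

# random mixed-type table with missingness, for property tests
random_mixed_table <- function(n, n_cont = 4, n_bin = 5, n_cat = 3,
                               miss = 0.05, seed = 1) {
  set.seed(seed)
  cols <- list()
  feats <- list()
  for (j in seq_len(n_cont)) {
    nm <- paste0("c", j)
    cols[[nm]] <- rnorm(n, mean = 10 * j, sd = runif(1, 0.5, 4))
    feats[[length(feats) + 1L]] <- data.frame(name = nm, kind = "continuous")
  }
  for (j in seq_len(n_bin)) {
    nm <- paste0("b", j)
    cols[[nm]] <- rbinom(n, 1, runif(1, 0.2, 0.8))
    feats[[length(feats) + 1L]] <- data.frame(name = nm, kind = "binary")
  }
  for (j in seq_len(n_cat)) {
    nm <- paste0("g", j)
    cols[[nm]] <- sample(letters[1:3], n, replace = TRUE)
    feats[[length(feats) + 1L]] <- data.frame(name = nm, kind = "categorical")
  }
  df <- as.data.frame(cols)
  if (miss > 0) {
    for (nm in names(df)) {
      hit <- runif(n) < miss
      df[[nm]][hit] <- NA
    }
    # guarantee at least one jointly observed feature per pair: keep the
    # first feature fully observed
    df[[1L]][is.na(df[[1L]])] <- 0
  }
  feature_table(df, feature_schema(do.call(rbind, feats)))
}

# exhaustive k-medoid optimum by enumerating all C(n, k) medoid sets
pam_exhaustive <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  combos <- utils::combn(n, k)
  for (j in seq_len(ncol(combos))) {
    med <- combos[, j]
    cost <- sum(apply(D[, med, drop = FALSE], 1L, min))
    if (cost < best) best <- cost
  }
  best
}

# random symmetric dissimilarity matrix with zero diagonal
random_dissimilarity <- function(n, seed) {
  set.seed(seed)
  D <- matrix(runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

# pair-enumeration adjusted Rand index: counts concordant / discordant
# point pairs directly
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# tiny ready-made cohort for IO tests
demo_schema <- function() {
  feature_schema(data.frame(
    name = c("age", "shock", "source"),
    kind = c("continuous", "binary", "categorical"),
    log_transform = c(FALSE, FALSE, FALSE)))
}

demo_table <- function() {
  feature_table(
    data.frame(age = c(40, 60, 90), shock = c(1L, 0L, 1L),
               source = c("lung", "urine", "lung")),
    demo_schema(), patient_ids = c("A", "B", "C"))
}
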