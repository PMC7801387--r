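# Independent oracles, deliberately naive: full boundary-matrix persistence
# by textbook reduction, all-pairs AUC counting, and a paired bootstrap for
# the DeLong variance. None of these share code with the package internals.

# Persistence of the full Rips filtration (dims 0-2) by reducing the whole
# boundary matrix over GF(2). Tractable only for tiny clouds (n <= ~25).
brute_rips_pairs <- function(cloud) {
  cloud <- as.matrix(cloud)
  n <- nrow(cloud)
  D <- as.matrix(stats::dist(cloud))
  simp <- list()   # each: list(verts, dim, filt)
  for (i in seq_len(n)) simp[[length(simp) + 1L]] <- list(v = i, dim = 0L, filt = 0)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    simp[[length(simp) + 1L]] <- list(v = c(i, j), dim = 1L, filt = D[i, j])
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    simp[[length(simp) + 1L]] <- list(v = c(i, j, k), dim = 2L,
                                      filt = max(D[i, j], D[i, k], D[j, k]))
  }
  ord <- order(vapply(simp, `[[`, numeric(1), "filt"),
               vapply(simp, `[[`, integer(1), "dim"))
  simp <- simp[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = "-"), character(1))
  pos <- stats::setNames(seq_along(simp), key)

  cols <- lapply(simp, function(s) {
    if (s$dim == 0L) return(integer(0))
    faces <- utils::combn(s$v, s$dim, simplify = FALSE)
    sort(unname(pos[vapply(faces, paste, character(1), collapse = "-")]))
  })
  low_of <- rep(NA_integer_, length(simp))   # row -> column claiming it
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    while (length(col)) {
      lw <- max(col)
      if (is.na(low_of[lw])) break
      other <- cols[[low_of[lw]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    if (length(col)) low_of[max(col)] <- j
  }
  pairs <- data.frame(birth = numeric(0), death = numeric(0), dim = integer(0))
  for (r in which(!is.na(low_of))) {
    pairs <- rbind(pairs, data.frame(
      birth = simp[[r]]$filt, death = simp[[low_of[r]]]$filt,
      dim = simp[[r]]$dim))
  }
  h1 <- pairs[pairs$dim == 1L & pairs$death > pairs$birth, c("birth", "death")]
  h0 <- pairs[pairs$dim == 0L & pairs$death > pairs$birth, c("birth", "death")]
  list(h0 = h0[order(h0$birth, h0$death), ],
       h1 = h1[order(h1$birth, h1$death), ])
}

# Mann-Whitney AUC by explicit all-pairs counting, ties as 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exhaustive operating-point sweep: max specificity with sensitivity >= target
brute_spec_at_sens <- function(scores, labels, target) {
  cuts <- sort(unique(c(-Inf, scores)))
  best <- c(sens = 1, spec = 0)
  for (ct in cuts) {
    pred <- scores > ct
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    if (sens >= target && spec > best[["spec"]]) best <- c(sens = sens, spec = spec)
  }
  best
}

# paired stratified bootstrap SD of AUC_a - AUC_b
boot_delong_sd <- function(score_a, score_b, labels, B = 1e5, seed = 42) {
  set.seed(seed)
  ipos <- which(labels == 1)
  ineg <- which(labels == 0)
  diffs <- vapply(seq_len(B), function(b) {
    rp <- sample(ipos, replace = TRUE)
    rn <- sample(ineg, replace = TRUE)
    idx <- c(rp, rn)
    lab <- c(rep(1, length(rp)), rep(0, length(rn)))
    brute_auc(score_a[idx], lab) - brute_auc(score_b[idx], lab)
  }, numeric(1))
  stats::sd(diffs)
}

# random point cloud fixtures for oracle-equivalence checks
random_clouds <- function(seed = 7, sizes = 4:8, dims = c(2, 3), reps = 2) {
  set.seed(seed)
  out <- list()
  for (np in sizes) for (d in dims) for (r in seq_len(reps)) {
    out[[length(out) + 1L]] <- matrix(stats::rnorm(np * d), np, d)
  }
  out
}

expect_diagrams_equal <- function(a, b, tol = 1e-10) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_equal(unname(as.matrix(a[order(a$birth, a$death), c("birth", "death")])),
                 unname(as.matrix(b[order(b$birth, b$death), c("birth", "death")])),
                 tolerance = tol)
  }
}
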