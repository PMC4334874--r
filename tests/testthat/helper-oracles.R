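# Shared fixtures and independent oracles used across the suite.

rnd_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(seq, p) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(x)) < p)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in hit) x[i] <- sample(alt[[x[i]]], 1)
  paste(x, collapse = "")
}

revcomp <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# ---- exhaustive ungapped local-alignment oracle ----------------------------
# Best-scoring ungapped segment over all diagonals of both strands
# (quadratic scan; Kadane maximum-subarray per diagonal with +match /
# -mismatch scores). Independent of the seeded X-drop matcher.
oracle_best_segment <- function(a, b, match = 1, mismatch = -2) {
  av <- utf8ToInt(a); na <- length(av)
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    bseq <- if (strand == "+") b else revcomp(b)
    bv <- utf8ToInt(bseq); nb <- length(bv)
    for (diag in (-(nb - 1)):(na - 1)) {
      i0 <- max(0, diag); j0 <- max(0, -diag)
      len <- min(na - i0, nb - j0)
      if (len < 1) next
      eq <- av[i0 + 1:len] == bv[j0 + 1:len]
      s <- ifelse(eq, match, mismatch)
      cs <- cumsum(s)
      prev_min <- cummin(c(0, cs[-len]))
      gain <- cs - prev_min
      t <- which.max(gain)
      if (gain[t] > best$score) {
        # start = position after the prefix minimum
        st <- which(c(0, cs)[1:t] == prev_min[t])[1] - 1L
        seg_eq <- eq[(st + 1):t]
        bs <- j0 + st; be <- j0 + t
        best <- list(score = gain[t], strand = strand,
                     a_start = i0 + st, a_end = i0 + t,
                     b_start = if (strand == "+") bs else nb - be,
                     b_end = if (strand == "+") be else nb - bs,
                     length = t - st, identities = sum(seg_eq))
      }
    }
  }
  best
}

# ---- independent greedy-with-trimming oracle -------------------------------
# Position-set reimplementation: footprints as explicit integer sets,
# identities recounted by comparing the actual sequences on every slice.
oracle_trim <- function(set, a_concat, b_concat, min_length) {
  h <- set$hsps
  o <- order(-h$score, -h$length, h$a_start, h$b_start)
  h <- h[o, , drop = FALSE]
  av <- strsplit(a_concat, "")[[1]]
  bv <- strsplit(b_concat, "")[[1]]
  used_a <- integer(0); used_b <- integer(0)
  res <- list()
  for (i in seq_len(nrow(h))) {
    hi <- h[i, ]
    offs <- 0:(hi$length - 1)
    apos <- hi$a_start + offs
    bpos <- if (hi$strand == "+") hi$b_start + offs else hi$b_end - 1 - offs
    ok <- !(apos %in% used_a) & !(bpos %in% used_b)
    if (!any(ok)) next
    # maximal runs of surviving offsets
    grp <- cumsum(c(TRUE, diff(which(ok)) > 1))
    for (g in split(which(ok), grp)) {
      if (length(g) < min_length) next
      ap <- apos[g]; bp <- bpos[g]
      achars <- av[ap + 1]
      bchars <- bv[bp + 1]
      if (hi$strand == "-")
        bchars <- chartr("ACGT", "TGCA", bchars)
      res[[length(res) + 1]] <- data.frame(
        a_start = min(ap), a_end = max(ap) + 1,
        b_start = min(bp), b_end = max(bp) + 1,
        strand = hi$strand, length = length(g),
        identities = sum(achars == bchars))
      used_a <- c(used_a, ap); used_b <- c(used_b, bp)
    }
  }
  if (length(res) == 0) return(NULL)
  out <- do.call(rbind, res)
  out[order(out$a_start, out$b_start), ]
}

# ---- pair-counting adjusted Rand oracle ------------------------------------
oracle_ari <- function(p, q) {
  q <- q[names(p)]
  n <- length(p)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- p[i] == p[j]; sq <- q[i] == q[j]
      if (sp && sq) n11 <- n11 + 1
      else if (!sp && !sq) n00 <- n00 + 1
      else if (sp) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- n11 + n10; nq <- n11 + n01; tot <- choose(n, 2)
  exp11 <- np * nq / tot
  den <- (np + nq) / 2 - exp11
  if (abs(den) < 1e-300) return(if (n10 + n01 == 0) 1 else 0)
  (n11 - exp11) / den
}

# ---- brute-force agglomerative oracle for threshold clustering -------------
# Same merge rule, naive membership-vector implementation.
oracle_threshold_cluster <- function(m, T, F) {
  labs <- rownames(m)
  memb <- setNames(seq_along(labs), labs)
  repeat {
    ids <- unique(memb)
    if (length(ids) < 2) break
    best <- NULL
    for (x in seq_along(ids)) {
      for (y in seq_len(length(ids))) {
        if (y <= x) next
        mi <- names(memb)[memb == ids[x]]
        mj <- names(memb)[memb == ids[y]]
        dd <- as.vector(m[mi, mj])
        if (sum(dd <= T) < 1 || mean(dd <= T) < F) next
        key <- sort(c(mi, mj))
        cand <- list(avg = mean(dd), x = ids[x], y = ids[y], key = key)
        take <- is.null(best) || cand$avg < best$avg - 1e-15 ||
          (abs(cand$avg - best$avg) <= 1e-15 &&
             paste(cand$key, collapse = "\r") <
               paste(best$key, collapse = "\r"))
        if (take) best <- cand
      }
    }
    if (is.null(best)) break
    memb[memb == best$y] <- best$x
  }
  partition(memb, T = T, F = F)
}

# canonical bipartitions (non-trivial) of an ape tree, for topology equality
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  sets <- lapply(parts, function(idx) sort(labs[idx]))
  canon <- lapply(sets, function(s) {
    if (tips[1] %in% s) sort(setdiff(tips, s)) else s
  })
  canon <- Filter(function(s) length(s) >= 2 && length(s) <= length(tips) - 2,
                  canon)
  unique(lapply(canon, unname))
}

# random labeled symmetric matrix with zero diagonal
rnd_dist <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  v <- runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# block-structured planted matrix: within-block distances ~ U(win), between
# ~ U(btw)
planted_dist <- function(sizes, win = c(0.01, 0.05), btw = c(0.4, 0.6)) {
  n <- sum(sizes)
  labels <- sprintf("t%02d", seq_len(n))
  blk <- rep(seq_along(sizes), sizes)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- if (blk[i] == blk[j]) runif(1, win[1], win[2])
           else runif(1, btw[1], btw[2])
      m[i, j] <- m[j, i] <- r
    }
  }
  list(m = m, truth = partition(setNames(blk, labels)))
}
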