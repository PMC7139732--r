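# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written as plain double loops, separate from the package's
# vectorized implementations.

dir_offsets <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
                    "90" = c(-1L, 0L), "135" = c(-1L, -1L))

# Pair-counting GLCM oracle: explicit loop over every pixel, symmetric
# accumulation, then normalization.
brute_glcm <- function(q, direction, levels) {
  off <- dir_offsets[[as.character(direction)]]
  m <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        i <- q[r, cc] + 1; j <- q[r2, c2] + 1
        m[i, j] <- m[i, j] + 1
        m[j, i] <- m[j, i] + 1
      }
    }
  }
  m / sum(m)
}

# Run-scanning GLRLM oracle: walks each scan line with a while loop.
brute_glrlm <- function(q, direction, levels) {
  nr <- nrow(q); nc <- ncol(q)
  lines <- list()
  if (direction == 0) {
    for (r in seq_len(nr)) lines[[length(lines) + 1]] <- q[r, ]
  } else if (direction == 90) {
    for (cc in seq_len(nc)) lines[[length(lines) + 1]] <- q[, cc]
  } else if (direction == 45) {
    for (s in 2:(nr + nc)) {
      ln <- c()
      for (r in seq(nr, 1)) {
        cc <- s - r
        if (cc >= 1 && cc <= nc) ln <- c(ln, q[r, cc])
      }
      lines[[length(lines) + 1]] <- ln
    }
  } else if (direction == 135) {
    for (s in (1 - nr):(nc - 1)) {
      ln <- c()
      for (r in seq_len(nr)) {
        cc <- s + r
        if (cc >= 1 && cc <= nc) ln <- c(ln, q[r, cc])
      }
      lines[[length(lines) + 1]] <- ln
    }
  }
  rmax <- max(vapply(lines, length, integer(1)))
  m <- matrix(0, levels, rmax)
  for (ln in lines) {
    k <- 1
    while (k <= length(ln)) {
      j <- k
      while (j < length(ln) && ln[j + 1] == ln[k]) j <- j + 1
      m[ln[k] + 1, j - k + 1] <- m[ln[k] + 1, j - k + 1] + 1
      k <- j + 1
    }
  }
  m
}

# Literal-formula GLCM feature oracle (0-based level values).
oracle_glcm_features <- function(p) {
  L <- nrow(p)
  ct <- en <- hom <- ent <- mu_i <- mu_j <- ac <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v <- p[i + 1, j + 1]
    ct <- ct + (i - j)^2 * v
    en <- en + v^2
    hom <- hom + v / (1 + abs(i - j))
    if (v > 0) ent <- ent - v * log2(v)
    mu_i <- mu_i + i * v; mu_j <- mu_j + j * v
    ac <- ac + i * j * v
  }
  si <- sj <- corr_num <- shade <- prom <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v <- p[i + 1, j + 1]
    si <- si + (i - mu_i)^2 * v
    sj <- sj + (j - mu_j)^2 * v
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * v
    shade <- shade + (i + j - mu_i - mu_j)^3 * v
    prom <- prom + (i + j - mu_i - mu_j)^4 * v
  }
  corr <- if (si <= 0 || sj <= 0) 1 else corr_num / sqrt(si * sj)
  c(glcm_contrast = ct, glcm_correlation = corr, glcm_energy = en,
    glcm_homogeneity = hom, glcm_entropy = ent, glcm_cluster_shade = shade,
    glcm_cluster_prominence = prom, glcm_autocorrelation = ac)
}

# Literal-formula GLRLM feature oracle (1-based gray level index).
oracle_glrlm_features <- function(g) {
  L <- nrow(g); R <- ncol(g)
  nr <- sum(g)
  lre <- sre <- hgl <- lgl <- srh <- srl <- lrh <- lrl <- 0
  for (i in 1:L) for (j in 1:R) {
    v <- g[i, j]
    lre <- lre + v * j^2;          sre <- sre + v / j^2
    hgl <- hgl + v * i^2;          lgl <- lgl + v / i^2
    srh <- srh + v * i^2 / j^2;    srl <- srl + v / (i^2 * j^2)
    lrh <- lrh + v * i^2 * j^2;    lrl <- lrl + v * j^2 / i^2
  }
  rln <- sum(sapply(1:R, function(j) sum(g[, j]))^2)
  gln <- sum(sapply(1:L, function(i) sum(g[i, ]))^2)
  c(glrlm_LRE = lre, glrlm_SRE = sre, glrlm_RLN = rln, glrlm_GLN = gln,
    glrlm_HGLRE = hgl, glrlm_LGLRE = lgl, glrlm_SRHGLE = srh,
    glrlm_SRLGLE = srl, glrlm_LRHGLE = lrh, glrlm_LRLGLE = lrl) / nr
}

# Loop-based first-order statistics oracle with manual linear-interpolation
# percentiles.
oracle_statistics <- function(patch) {
  x <- sort(as.numeric(patch))
  n <- length(x)
  m <- sum(x) / n
  ctr <- x - m
  m2 <- sum(ctr^2) / n
  pct <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  c(mean = m,
    std = sqrt(sum(ctr^2) / (n - 1)),
    median = pct(0.5),
    skewness = if (m2 == 0) 0 else (sum(ctr^3) / n) / m2^1.5,
    kurtosis = if (m2 == 0) 0 else (sum(ctr^4) / n) / m2^2,
    max = x[n], min = x[1],
    sapply(seq(0.1, 0.9, 0.1), pct))
}

# Binary shape builders on a bright background.
shape_image <- function(mask, fg = 60L, bg = 200L) {
  img <- matrix(bg, nrow(mask), ncol(mask))
  img[mask] <- fg
  storage.mode(img) <- "integer"
  img
}

disk_mask <- function(n, ctr, r) {
  (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2 <= r^2
}

ellipse_mask <- function(n, ctr, a_cols, b_rows) {
  ((col(matrix(0, n, n)) - ctr) / a_cols)^2 +
    ((row(matrix(0, n, n)) - ctr) / b_rows)^2 <= 1
}

rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Direct feature-table generator: three layers with independent class signal,
# bypassing image rendering. Used where the property under test concerns the
# classifier stack, not the feature extractors.
make_feature_table <- function(n, d_conv = 1.5, d_tex = 1.5, d_clin = 1,
                               n_informative = 3, seed = 1) {
  withr::with_seed(seed, {
    grade <- sample(rep(c("LGG", "HGG"), length.out = n))
    shift <- as.numeric(grade == "HGG")
    tab <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      grade = factor(grade, c("LGG", "HGG")),
      clin_age = rnorm(n, 43.19 + 13.6 * shift * d_clin, 12),
      clin_gender = rbinom(n, 1, 0.58),
      stringsAsFactors = FALSE
    )
    for (i in 1:26)
      tab[[sprintf("conv_f%02d", i)]] <-
        rnorm(n) + (i <= n_informative) * d_conv * shift
    for (i in 1:18)
      tab[[sprintf("tex_f%02d", i)]] <-
        rnorm(n) + (i <= n_informative) * d_tex * shift
    tab
  })
}

make_runs <- function(aucs, id = "X", seeds = seq_along(aucs)) {
  structure(list(model_id = id, aucs = aucs, seeds = seeds),
            class = "permutation_runs")
}
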