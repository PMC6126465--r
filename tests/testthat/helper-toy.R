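# Small hand-built fixtures used across the suite.

# A toy dataset with explicit observations.
toy_dataset <- function(obs, cell = unit_cell(10, 10, 10, 90, 90, 90),
                        sg = "P1", first = 1L, last = max(obs$image),
                        serial = 1L, id = "toy") {
  unmerged_dataset(id, cell, sg, obs, first, last, serial = serial)
}

# Random valid canonical dataset for round-trip properties.
random_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(3:40, 1)
  last <- sample(5:30, 1)
  obs <- data.frame(h = sample(-5:5, n, TRUE), k = sample(-5:5, n, TRUE),
                    l = sample(1:5, n, TRUE),
                    intensity = round(stats::rnorm(n, 100, 40), 4),
                    sigma = round(stats::runif(n, 0.5, 9), 4),
                    image = sample(seq_len(last), n, TRUE))
  cellv <- c(round(stats::runif(3, 20, 90), 3), round(stats::runif(3, 75, 105), 3))
  ds <- try(unmerged_dataset(sprintf("rand%03d", seed), cellv, "P1", obs, 1L, last,
                             serial = 1L), silent = TRUE)
  if (inherits(ds, "try-error")) random_dataset(seed + 1000) else ds
}

# Independent LCV/aLCV oracle: own trig for the diagonals, explicit loops.
oracle_metrics <- function(cells) {
  diags <- function(cl) {
    cl <- as.numeric(cl)
    f <- function(p, q, th) {
      c1 <- sqrt(p^2 + q^2 - 2 * p * q * cos(th * pi / 180))
      c2 <- sqrt(p^2 + q^2 + 2 * p * q * cos(th * pi / 180))
      max(c1, c2)
    }
    c(f(cl[1], cl[2], cl[6]), f(cl[2], cl[3], cl[4]), f(cl[1], cl[3], cl[5]))
  }
  D <- t(sapply(cells, diags))
  best_a <- 0; best_l <- 0
  for (i in seq_along(cells)) for (j in seq_along(cells)) for (f in 1:3) {
    if (i == j) next
    d <- abs(D[i, f] - D[j, f])
    best_a <- max(best_a, d)
    best_l <- max(best_l, 100 * d / min(D[i, f], D[j, f]))
  }
  c(lcv = best_l, alcv = best_a)
}

# Exhaustive unique-reflection count oracle (independent loops, own d calc).
oracle_unique_count <- function(cell, sg, d_min, lim = 6) {
  cl <- as.numeric(cell)
  seen <- character(0)
  rot_sets <- list(
    P1 = list(diag(3)),
    P21 = list(diag(3), diag(c(-1, 1, -1))))
  rots <- rot_sets[[sg]]
  for (h in -lim:lim) for (k in -lim:lim) for (l in -lim:lim) {
    if (h == 0 && k == 0 && l == 0) next
    v <- c(h, k, l)
    G <- isomerge:::cell_metric(as_unit_cell(cl))
    s <- drop(t(v) %*% solve(G) %*% v)
    if (s > 1 / d_min^2 + 1e-12) next
    orbit <- unlist(lapply(rots, function(R) {
      w <- drop(v %*% R)
      list(paste(w, collapse = ","), paste(-w, collapse = ","))
    }))
    key <- sort(orbit)[1]
    seen <- c(seen, key)
  }
  length(unique(seen))
}
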