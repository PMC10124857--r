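# Independent oracles used across the suite. Deliberately written as naive,
# direct implementations so they share no code with the package internals.

# brute-force grid minimizer of the turnover RSS over (disc, tau)
grid_fit_turnover <- function(obs, delta0,
                              disc_range = c(-5, 5), tau_range = c(0.001, 0.1),
                              n_grid = 400) {
  disc_grid <- seq(disc_range[1], disc_range[2], length.out = n_grid)
  tau_grid <- seq(tau_range[1], tau_range[2], length.out = n_grid)
  best <- c(NA, NA)
  best_rss <- Inf
  for (tau in tau_grid) {
    e <- exp(-tau * obs$day)
    # pred = (prey + disc) + (delta0 - prey - disc) e  =  a + disc (1 - e)
    a <- obs$delta_prey + (delta0 - obs$delta_prey) * e
    # residual matrix: rows obs, cols disc grid
    r <- outer(obs$value - a, rep(1, n_grid)) -
      outer(1 - e, disc_grid)
    rss <- colSums(r^2)
    k <- which.min(rss)
    if (rss[k] < best_rss) {
      best_rss <- rss[k]
      best <- c(disc_grid[k], tau)
    }
  }
  list(disc = best[1], tau = best[2], rss = best_rss,
       cell = c(disc = diff(disc_range) / (n_grid - 1),
                tau = diff(tau_range) / (n_grid - 1)))
}

# direct, independently coded evaluation of the two-source mixing likelihood
# (long-hand Gaussian density, no dnorm)
direct_mixing_loglik <- function(p_vec, sigma_res, x, mu, sig, tef_mean, tef_sd) {
  total <- 0
  for (i in 1:2) {
    m <- 0
    v <- sigma_res[i]^2
    for (k in seq_along(p_vec)) {
      m <- m + p_vec[k] * (mu[k, i] + tef_mean[i])
      v <- v + p_vec[k]^2 * (sig[k, i]^2 + tef_sd[i]^2)
    }
    for (j in seq_len(nrow(x))) {
      total <- total - 0.5 * log(2 * pi * v) - (x[j, i] - m)^2 / (2 * v)
    }
  }
  total
}

# brute-force grid posterior for the two-source model: p on np points,
# per-isotope residual SD marginalized on ns points over (0, 20).
# The likelihood factorizes over isotopes given p, so each sigma grid can be
# summed out independently.
grid_mixing_median <- function(consumers, sources, tef, np = 2000, ns = 200,
                               first_source = NULL) {
  iso <- c("C13", "N15")
  src <- unique(sources$source)
  if (!is.null(first_source)) src <- c(first_source, setdiff(src, first_source))
  stopifnot(length(src) == 2)
  mu <- sapply(iso, function(i) sources$mean[match(paste(src, i), paste(sources$source, sources$isotope))])
  sg <- sapply(iso, function(i) sources$sd[match(paste(src, i), paste(sources$source, sources$isotope))])
  tm <- tef$mean[match(iso, tef$isotope)]
  ts <- tef$sd[match(iso, tef$isotope)]
  c_col <- if ("d13c_norm" %in% names(consumers)) "d13c_norm" else "d13c"
  x <- cbind(consumers[[c_col]], consumers$d15n)

  p_grid <- seq(1e-6, 1 - 1e-6, length.out = np)
  s_grid <- seq(1e-3, 20 - 1e-3, length.out = ns)
  log_w <- numeric(np)
  for (i in 1:2) {
    m <- p_grid * (mu[1, i] + tm[i]) + (1 - p_grid) * (mu[2, i] + tm[i])
    v_mix <- p_grid^2 * (sg[1, i]^2 + ts[i]^2) + (1 - p_grid)^2 * (sg[2, i]^2 + ts[i]^2)
    # matrix np x ns of log-likelihoods, then log-sum-exp over sigma
    ll <- sapply(s_grid, function(s) {
      v <- v_mix + s^2
      -nrow(x) / 2 * log(2 * pi * v) - colSums(outer(x[, i], m, "-")^2) / (2 * v)
    })
    lmax <- apply(ll, 1, max)
    log_w <- log_w + lmax + log(rowSums(exp(ll - lmax)))
  }
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  p_grid[which(cumsum(w) >= 0.5)[1]]
}

# naive filter-and-count FOO recount
oracle_foo <- function(records, taxon) {
  denom <- 0
  num <- 0
  for (j in seq_len(nrow(records))) {
    if (isTRUE(records$has_identifiable_content[j])) {
      denom <- denom + 1
      if (records[[taxon]][j] > 0) num <- num + 1
    }
  }
  100 * num / denom
}

# build a small gut table directly (counts matrix by taxon)
make_guts <- function(lengths, counts, empty = NULL, unident = NULL) {
  n <- length(lengths)
  counts <- as.data.frame(counts)
  any_prey <- rowSums(counts) > 0
  is_empty <- if (is.null(empty)) rep(FALSE, n) else empty
  has_id <- if (is.null(unident)) any_prey & !is_empty else any_prey | (!is_empty & !unident)
  dplyr::bind_cols(
    tibble::tibble(fish_id = as.character(seq_len(n)), length_mm = lengths,
                   is_empty = is_empty, has_identifiable_content = has_id & !is_empty),
    tibble::as_tibble(counts)
  )
}

# random gut table for property tests
random_guts <- function(n, seed, taxa = c("chironomid", "dreissenid", "cladoceran")) {
  set.seed(seed)
  counts <- sapply(taxa, function(t) rpois(n, 0.8))
  state <- sample(c("empty", "unident", "content"), n, replace = TRUE,
                  prob = c(0.1, 0.05, 0.85))
  counts[state != "content", ] <- 0L
  tibble::tibble(
    fish_id = sprintf("f%04d", seq_len(n)),
    length_mm = sample(17:120, n, replace = TRUE),
    is_empty = state == "empty",
    has_identifiable_content = state == "content" & rowSums(counts) > 0
  ) |> dplyr::bind_cols(tibble::as_tibble(counts))
}
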