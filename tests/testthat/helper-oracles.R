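# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Solar position by the Astronomical Almanac low-precision algorithm
# (Michalsky-style ecliptic-coordinate route, J2000-referenced constants).
# Completely independent of the NOAA equation-of-time route the package uses.
oracle_solar_position <- function(time_utc, lat, lon) {
  d2r <- pi / 180
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  time <- jd - 2451545.0
  hour <- (as.numeric(time_utc) %% 86400) / 3600
  mnlong <- (280.460 + 0.9856474 * time) %% 360
  mnanom <- (357.528 + 0.9856003 * time) %% 360
  eclong <- (mnlong + 1.915 * sin(mnanom * d2r) + 0.020 * sin(2 * mnanom * d2r)) %% 360
  oblqec <- 23.439 - 4e-07 * time
  ra <- atan2(cos(oblqec * d2r) * sin(eclong * d2r), cos(eclong * d2r)) %% (2 * pi)
  dec <- asin(sin(oblqec * d2r) * sin(eclong * d2r))
  gmst <- (6.697375 + 0.0657098242 * time + hour) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- ((lmst * 15 - ra / d2r + 180) %% 360 - 180) * d2r
  el <- asin(sin(dec) * sin(lat * d2r) + cos(dec) * cos(lat * d2r) * cos(ha))
  az <- (atan2(sin(ha), cos(ha) * sin(lat * d2r) - tan(dec) * cos(lat * d2r)) / d2r + 180) %% 360
  data.frame(azimuth = az, elevation = el / d2r)
}

# cosine similarity between two spectra
cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best assignment of estimated spectra (rows) to reference spectra (columns)
# by exhaustive permutation of the smaller dimension (k <= 4 in the suite)
match_components <- function(est, ref) {
  k <- nrow(est)
  stopifnot(ncol(ref) == k)
  perms <- permute_all(seq_len(k))
  scores <- vapply(perms, function(p) {
    sum(vapply(seq_len(k), function(i) cosine_sim(est[i, ], ref[, p[i]]), numeric(1)))
  }, numeric(1))
  best <- perms[[which.max(scores)]]
  vapply(seq_len(k), function(i) cosine_sim(est[i, ], ref[, best[i]]), numeric(1))
}

permute_all <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permute_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# classical balanced two-way ANOVA by explicit sums of squares
oracle_two_way_anova <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  grand <- mean(y)
  n_cell <- table(a, b)
  stopifnot(length(unique(as.vector(n_cell))) == 1L) # balanced only
  nc <- n_cell[1, 1]
  mean_a <- tapply(y, a, mean)
  mean_b <- tapply(y, b, mean)
  mean_ab <- tapply(y, interaction(a, b), mean)
  ss_a <- nc * nlevels(b) * sum((mean_a - grand)^2)
  ss_b <- nc * nlevels(a) * sum((mean_b - grand)^2)
  ss_tot <- sum((y - grand)^2)
  cell_of <- interaction(a, b)
  ss_err <- sum((y - mean_ab[cell_of])^2)
  ss_ab <- ss_tot - ss_a - ss_b - ss_err
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  df_err <- length(y) - nlevels(a) * nlevels(b)
  ms_err <- ss_err / df_err
  data.frame(
    term = c("a", "b", "a:b"),
    F = c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / ms_err
  )
}

# brute-force Mann-Whitney U from rank sums
oracle_u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  rx <- sum(r[seq_along(x)])
  rx - length(x) * (length(x) + 1) / 2
}

# textbook Kruskal-Wallis H without tie correction wrapper (ties handled
# through midranks + correction term)
oracle_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ng) - 3 * (n + 1)
  ties <- table(r)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# a small conductance series wrapper for constructed toy vectors
toy_conductance_series <- function(g, t_mid = seq_along(g)) {
  out <- tibble::tibble(
    t_mid = t_mid, dt_h = c(diff(t_mid), diff(t_mid)[length(t_mid) - 1]),
    E = g, g = g, phase = "unassigned"
  )
  class(out) <- c("conductance_series", class(out))
  out
}
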