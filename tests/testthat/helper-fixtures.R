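# shared fixtures and independent oracles for the test suite

# tiny hand-written supported-housing table (values chosen for easy arithmetic)
toy_services <- function(care_type = "supported_housing", n = 6) {
  df <- data.frame(
    service_id = sprintf("svc_%02d", seq_len(n)),
    care_type = care_type,
    places = rep(c(10, 20, 15), length.out = n),
    staff_fte_per_user = rep(c(0.4, 0.6, 0.5), length.out = n),
    annual_budget = rep(c(250000, 500000, 400000), length.out = n),
    length_of_stay = rep(c(1.5, 2.5, 2), length.out = n),
    occupied_places = rep(c(9, 19, 12), length.out = n),
    movers_2yr = rep(c(4, 6, 5), length.out = n),
    outlier_flag = FALSE,
    stringsAsFactors = FALSE
  )
  for (d in quirc_domains(care_type))
    df[[paste0("quirc_", d)]] <- rep(c(60, 75, 70), length.out = n) +
      seq_len(n) %% 3
  df
}

# independent random DEA instance (strictly positive data)
random_instance <- function(d, ni, nj) {
  list(X = matrix(runif(d * ni, 0.5, 10), d, ni),
       Y = matrix(runif(d * nj, 0.5, 10), d, nj))
}

# independent exact two-sided signed-rank p-value by full sign enumeration
# (average ranks for tied absolute differences)
enum_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^n
  vs <- numeric(total)
  for (k in 0:(total - 1)) {
    bits <- as.integer(intToBits(k))[seq_len(n)]
    vs[k + 1] <- sum(r[bits == 1L])
  }
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}
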