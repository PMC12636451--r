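#' Specify a lifespan simulation
#'
#' Describes one or more genotype cohorts whose death times follow a
#' Gompertz mortality law, h(t) = alpha * exp(beta * t), censused at a
#' fixed cadence in vials. Defaults mirror a standard fly-room protocol:
#' twice-weekly transfers (census every 3.5 days) at a density of at most
#' 15 flies per vial, 100 flies per genotype.
#'
#' @param genotypes data.frame with columns `label`, `alpha` (hazard per
#'   day at t = 0, > 0), `beta` (aging rate per day, >= 0) and `n_flies`.
#' @param census_interval_days census cadence in days (default 3.5).
#' @param max_flies_per_vial vial occupancy cap (default 15).
#' @param seed integer seed for the generator's private RNG stream.
#' @return object of class `lifespan_sim_spec`.
#' @seealso [simulate_lifespans()]
#' @export
lifespan_sim_spec <- function(genotypes,
                              census_interval_days = 3.5,
                              max_flies_per_vial = 15,
                              seed = 1L) {
  stop_if(!is.data.frame(genotypes) ||
            !all(c("label", "alpha", "beta", "n_flies") %in% names(genotypes)),
          "'genotypes' needs columns label, alpha, beta, n_flies")
  stop_if(nrow(genotypes) < 1L, "at least one genotype required")
  for (i in seq_len(nrow(genotypes))) {
    check_number(genotypes$alpha[i], "alpha", lower = 0)
    check_number(genotypes$beta[i], "beta", lower = 0, allow_equal_lower = TRUE)
    check_count(genotypes$n_flies[i], "n_flies", min = 1L)
  }
  check_number(census_interval_days, "census_interval_days", lower = 0)
  check_count(max_flies_per_vial, "max_flies_per_vial", min = 1L)
  structure(list(genotypes = genotypes,
                 census_interval_days = census_interval_days,
                 max_flies_per_vial = as.integer(max_flies_per_vial),
                 seed = as.integer(seed)),
            class = "lifespan_sim_spec")
}

#' Draw Gompertz death times by inverse-CDF sampling
#'
#' S(t) = exp(-(alpha/beta) * (exp(beta t) - 1)); solving S(t) = u gives
#' t = log1p(-(beta/alpha) * log u) / beta, with the exponential limit
#' t = -log(u)/alpha at beta = 0.
#'
#' @param n number of draws.
#' @param alpha baseline hazard per day (> 0).
#' @param beta aging rate per day (>= 0).
#' @return vector of death times in days.
#' @export
rgompertz_time <- function(n, alpha, beta) {
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0, allow_equal_lower = TRUE)
  u <- runif(n)
  if (beta < 1e-12) return(-log(u) / alpha)
  log1p(-(beta / alpha) * log(u)) / beta
}

#' Gompertz survival function
#'
#' @param t times in days.
#' @param alpha,beta Gompertz parameters (beta = 0 gives the exponential).
#' @return S(t).
#' @export
gompertz_survival <- function(t, alpha, beta) {
  if (beta < 1e-12) return(exp(-alpha * t))
  exp(-(alpha / beta) * expm1(beta * t))
}

#' Simulate a vial-census survival table
#'
#' Death times are drawn per fly from the Gompertz law, flies are assigned
#' round-robin to vials (at most `max_flies_per_vial` each), and deaths are
#' recorded at the first census following death; the reported `census_day`
#' is the interval right endpoint, as in twice-weekly counting. Cohorts are
#' followed until all flies have died, so no censoring arises by default.
#'
#' @param spec a [lifespan_sim_spec()].
#' @return a `survival_table`: data.frame with columns genotype, vial,
#'   census_day, deaths, censored, plus attribute `initial_n` (per-vial
#'   occupancy).
#' @export
simulate_lifespans <- function(spec) {
  stop_if(!inherits(spec, "lifespan_sim_spec"), "need a lifespan_sim_spec")
  with_seed(spec$seed, {
    out <- vector("list", nrow(spec$genotypes))
    for (g in seq_len(nrow(spec$genotypes))) {
      lab <- as.character(spec$genotypes$label[g])
      n <- spec$genotypes$n_flies[g]
      tdeath <- rgompertz_time(n, spec$genotypes$alpha[g],
                               spec$genotypes$beta[g])
      n_vials <- ceiling(n / spec$max_flies_per_vial)
      vial <- rep_len(seq_len(n_vials), n)
      census_day <- ceiling(tdeath / spec$census_interval_days) *
        spec$census_interval_days
      census_day[census_day <= 0] <- spec$census_interval_days
      tab <- as.data.frame(table(vial = vial, census_day = census_day),
                           stringsAsFactors = FALSE)
      tab <- tab[tab$Freq > 0L, ]
      out[[g]] <- data.frame(
        genotype = lab,
        vial = paste0(lab, "_v", tab$vial),
        census_day = as.numeric(tab$census_day),
        deaths = tab$Freq,
        censored = 0L,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res <- res[order(res$genotype, res$vial, res$census_day), ]
    rownames(res) <- NULL
    as_survival_table(res)
  })
}

#' Construct/validate a survival table
#'
#' @param df data.frame with columns genotype, vial, census_day, deaths,
#'   censored. Census days must be strictly increasing within vial.
#' @return the validated data.frame with class `survival_table` and an
#'   `initial_n` attribute (deaths + censored per vial).
#' @export
as_survival_table <- function(df) {
  need <- c("genotype", "vial", "census_day", "deaths", "censored")
  stop_if(!is.data.frame(df) || !all(need %in% names(df)),
          "survival table needs columns genotype, vial, census_day, deaths, censored")
  stop_if(any(df$deaths < 0) || any(df$censored < 0),
          "deaths and censored must be nonnegative")
  stop_if(any(df$census_day < 0), "census_day must be >= 0")
  for (v in unique(df$vial)) {
    cd <- df$census_day[df$vial == v]
    stop_if(is.unsorted(cd, strictly = TRUE),
            sprintf("census days must be strictly increasing within vial '%s'", v))
  }
  initial_n <- tapply(df$deaths + df$censored, df$vial, sum)
  structure(df, class = c("survival_table", "data.frame"),
            initial_n = initial_n)
}

#' @export
print.survival_table <- function(x, ...) {
  cat(sprintf("Vial-census survival table: %d genotypes, %d vials, %d flies\n",
              length(unique(x$genotype)), length(unique(x$vial)),
              sum(x$deaths + x$censored)))
  NextMethod()
}

#' Write / read a survival table CSV
#'
#' @param x a `survival_table`.
#' @param path output CSV path.
#' @return `path`, invisibly (writer); a `survival_table` (reader).
#' @export
write_survival_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) as_survival_table(read.csv(path))
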