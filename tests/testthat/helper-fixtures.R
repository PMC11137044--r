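# shared fixtures: reference sites, a fast MCMC config for smoke-level fits,
# and a neutral windchill parameter set with only one active term.

pg_site <- function() colony_site("Pointe Geologie", -(66 + 40 / 60), 140 + 1 / 60)
ab_site <- function() colony_site("Atka Bay", -(70 + 40 / 60), -(8 + 16 / 60))

tiny_mcmc <- function(n_walkers = 8, n_burn = 150, n_keep = 150) {
  mcmc_defaults(n_walkers = n_walkers, n_burn = n_burn, n_keep = n_keep)
}

# windchill params where T_a == temp_c (no wind/sun/humidity terms)
wc_plain <- function(T_c = -10, b_0 = 4) {
  windchill_params(c_W = 0, c_R = 0, c_H = 0, T_c = T_c, b_0 = b_0)
}

weather_row <- function(temp_c = -10, wind_ms = 0, rad_wm2 = 0, rh_pct = 0,
                        timestamp = as.POSIXct("2019-10-01 04:00:00", tz = "UTC")) {
  tibble::tibble(timestamp = timestamp, temp_c = temp_c, wind_ms = wind_ms,
                 rad_wm2 = rad_wm2, rh_pct = rh_pct)
}
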