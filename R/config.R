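# Pipeline and simulation configuration objects.

#' Pipeline configuration
#'
#' Bundles the tunable parameters shared by the processing stages.
#'
#' @param z_threshold positive number; per-axis absolute z-score above which a
#'   fix is flagged erroneous. Default 4.5.
#' @param utm_zone UTM zone designation, default `"13N"` (the study site in
#'   northeastern New Mexico).
#' @param day_timezone IANA time-zone string defining the calendar day used to
#'   group fixes. Default `"UTC"` for reproducibility; use the site zone
#'   (e.g. `"America/Denver"`) for geographic fidelity.
#' @param min_fixes_per_day integer >= 2; tracker-days with fewer fixes are
#'   treated as degenerate: no outlier flags, distance 0.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"` for
#'   the z-score standard deviation.
#' @param degenerate_day `"zero"` (default) to report 0 m for tracker-days
#'   with fewer than 2 surviving fixes, `"na"` to report a missing distance.
#' @param rng_seed integer seed used by stages that draw random numbers.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(z_threshold = 4.5,
                            utm_zone = "13N",
                            day_timezone = "UTC",
                            min_fixes_per_day = 2L,
                            sd_type = c("sample", "population"),
                            degenerate_day = c("zero", "na"),
                            rng_seed = 1L) {
  sd_type <- match.arg(sd_type)
  degenerate_day <- match.arg(degenerate_day)
  stopifnot(is.numeric(z_threshold), length(z_threshold) == 1, z_threshold > 0)
  min_fixes_per_day <- as.integer(min_fixes_per_day)
  if (is.na(min_fixes_per_day) || min_fixes_per_day < 2)
    stop("min_fixes_per_day must be an integer >= 2")
  parse_utm_zone(utm_zone)  # validate early
  structure(list(z_threshold = z_threshold,
                 utm_zone = utm_zone,
                 day_timezone = day_timezone,
                 min_fixes_per_day = min_fixes_per_day,
                 sd_type = sd_type,
                 degenerate_day = degenerate_day,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

# radius holding 95% of an isotropic bivariate Gaussian -> per-axis sd
# R95 = sigma * sqrt(-2 log(0.05))
.r95_to_sigma <- function(r95) r95 / sqrt(-2 * log(0.05))

#' Simulation scenario
#'
#' Describes a synthetic deployment: static reference trackers indoors (GPS
#' view obstructed by the building) and outdoors (clear sky), plus collared
#' animals whose movement alternates rest and active bouts.  Defaults emulate
#' the deployment the pipeline was designed around: 5 indoor + 6 outdoor
#' static trackers and 6 animal trackers, GPS every 15 min, motion counts
#' every 1 min, 7 analyzed days per phase, and position error calibrated so
#' 95% of static fixes fall within 15 m (outdoor) / 40 m (indoor) of truth.
#'
#' @param n_animal,n_indoor,n_outdoor tracker counts per placement.
#' @param days analyzed days per deployment phase (>= 1).
#' @param gps_interval_min minutes between scheduled GPS fixes.
#' @param motion_interval_min minutes between motion (Motion Index) reports.
#' @param fix_dropout_prob probability a scheduled fix fails (independent
#'   Bernoulli per fix).
#' @param r95_outdoor_m,r95_indoor_m radius (m) containing 95% of static
#'   position errors for clear-sky and obstructed trackers.
#' @param outlier_prob per-fix probability of a gross position error.
#' @param outlier_range_m two numbers; gross errors displace the fix by a
#'   log-uniform distance in this range (m), random direction.
#' @param noise_df if finite, per-axis noise is Student-t with this many
#'   degrees of freedom (scaled to the same R95) instead of Gaussian; use to
#'   stress the outlier filter with heavy tails. Default `Inf` (Gaussian).
#' @param p_rest_to_active,p_active_to_rest per-minute transition
#'   probabilities of the two-state (rest/active) movement chain.
#' @param step_mean_m_per_min mean step length during an active minute (m);
#'   drawn from a gamma distribution with `step_shape`.
#' @param step_shape gamma shape of the active step length.
#' @param turn_sd_rad standard deviation of the per-minute heading increment
#'   (rad); smaller = straighter, more persistent travel.
#' @param mi_active_mean mean Motion Index count per active minute (Poisson).
#' @param spurious_mi_prob probability a resting/static minute still reports
#'   a positive Motion Index (sensor noise). Default 0.
#' @param site_lat,site_lon deployment site origin (WGS84 degrees).
#' @param static_start,animal_start first analyzed calendar day (UTC) of the
#'   static and animal deployment phases; the two phases are disjoint in
#'   time, as in a staged field deployment.
#' @param rng_seed integer seed; the whole file set is a deterministic
#'   function of the scenario including this seed.
#' @return a list of class `sim_scenario`.
#' @details With the default movement parameters the stationary probability
#'   of the active state is `p_rest_to_active / (p_rest_to_active +
#'   p_active_to_rest)` = 0.4, i.e. about 576 active minutes/day, and the
#'   expected true path is about 576 * 4.5 = 2.6 km/day, the magnitude
#'   reported for collared cows on winter pasture.
#' @export
sim_scenario <- function(n_animal = 6L, n_indoor = 5L, n_outdoor = 6L,
                         days = 7L,
                         gps_interval_min = 15L,
                         motion_interval_min = 1L,
                         fix_dropout_prob = 0.1,
                         r95_outdoor_m = 15,
                         r95_indoor_m = 40,
                         outlier_prob = 0.005,
                         outlier_range_m = c(5e3, 5e5),
                         noise_df = Inf,
                         p_rest_to_active = 0.02,
                         p_active_to_rest = 0.03,
                         step_mean_m_per_min = 4.5,
                         step_shape = 2,
                         turn_sd_rad = 0.6,
                         mi_active_mean = 5,
                         spurious_mi_prob = 0,
                         site_lat = 36.45,
                         site_lon = -103.15,
                         static_start = "2020-11-12",
                         animal_start = "2020-12-25",
                         rng_seed = 1L) {
  sc <- list(n_animal = as.integer(n_animal), n_indoor = as.integer(n_indoor),
             n_outdoor = as.integer(n_outdoor), days = as.integer(days),
             gps_interval_min = as.integer(gps_interval_min),
             motion_interval_min = as.integer(motion_interval_min),
             fix_dropout_prob = fix_dropout_prob,
             r95_outdoor_m = r95_outdoor_m, r95_indoor_m = r95_indoor_m,
             sigma_outdoor_m = .r95_to_sigma(r95_outdoor_m),
             sigma_indoor_m = .r95_to_sigma(r95_indoor_m),
             outlier_prob = outlier_prob, outlier_range_m = outlier_range_m,
             noise_df = noise_df,
             p_rest_to_active = p_rest_to_active,
             p_active_to_rest = p_active_to_rest,
             step_mean_m_per_min = step_mean_m_per_min,
             step_shape = step_shape, turn_sd_rad = turn_sd_rad,
             mi_active_mean = mi_active_mean,
             spurious_mi_prob = spurious_mi_prob,
             site_lat = site_lat, site_lon = site_lon,
             static_start = static_start, animal_start = animal_start,
             rng_seed = as.integer(rng_seed))
  stopifnot(sc$days >= 1,
            sc$fix_dropout_prob >= 0, sc$fix_dropout_prob <= 1,
            sc$outlier_prob >= 0, sc$outlier_prob <= 1,
            sc$spurious_mi_prob >= 0, sc$spurious_mi_prob <= 1,
            sc$p_rest_to_active >= 0, sc$p_rest_to_active <= 1,
            sc$p_active_to_rest >= 0, sc$p_active_to_rest <= 1,
            sc$sigma_outdoor_m >= 0, sc$sigma_indoor_m >= 0)
  class(sc) <- "sim_scenario"
  sc
}
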