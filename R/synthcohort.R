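#' Closed-form expected phase-locking value for von Mises jitter
#'
#' For a pair whose phase difference is von Mises distributed with
#' concentration `kappa`, the population PLV is the ratio of modified Bessel
#' functions `I1(kappa)/I0(kappa)`. `kappa = 0` gives 0 (independent phases),
#' `kappa -> Inf` gives 1 (perfect locking). For `kappa > 100` the asymptotic
#' expansion `1 - 1/(2k) - 1/(8k^2)` is used (besselI overflows there).
#'
#' @param kappa Non-negative von Mises concentration (vectorized).
#' @return Expected PLV in `[0, 1]`.
#' @examples
#' expected_plv(c(0, 2, 1e6))
#' @export
expected_plv <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  vapply(kappa, function(k) {
    if (k == 0) return(0)
    if (k > 100) return(1 - 1 / (2 * k) - 1 / (8 * k^2))
    besselI(k, 1) / besselI(k, 0)
  }, numeric(1))
}

#' Simulation specification for a synthetic source-level cohort subject
#'
#' Defines one subject's generative model: per-band oscillation amplitudes,
#' pairwise phase coupling (von Mises concentration per region pair and band),
#' 1/f background noise level, and the master seed. Every random stream is a
#' deterministic function of `seed`, so the same spec reproduces the same
#' series bit for bit.
#'
#' Coupled pairs within a band must form star-shaped groups: each connected
#' component of the coupling graph has a reference region (its lowest index)
#' and every coupled pair in the component must include it. The reference
#' carries the shared band phase; the other members add von Mises jitter with
#' their pair's `kappa`, which makes the expected PLV against the reference
#' exactly `I1(kappa)/I0(kappa)` and the expected PLV between two non-reference
#' members the product of their two ratios.
#'
#' @param n_regions Number of cortical regions (default 68).
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration Recording length in seconds (>= 10).
#' @param band_amplitudes Named numeric vector of oscillation amplitudes per
#'   canonical band (defaults to 1 for all four bands).
#' @param coupling Data frame with columns `i`, `j` (region indices), `band`
#'   (canonical band name) and `kappa` (>= 0). `kappa = 0` rows are dropped
#'   (independent phases).
#' @param noise_sd Standard deviation of the 1/f background (default 0.25).
#' @param planted_edges Optional m x 2 integer matrix marking the pairs that
#'   constitute the planted subnetwork (recorded in the ground truth; the
#'   corresponding coupling rows must still be present in `coupling`).
#' @param seed Integer master seed (required).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_regions = 68, fs = 1000, duration,
                            band_amplitudes = NULL, coupling = NULL,
                            noise_sd = 0.25, planted_edges = NULL, seed) {
  if (missing(duration) || !is.numeric(duration) || duration <= 0)
    stop("invalid simulation spec: duration must be a positive number of seconds")
  if (duration < 10)
    stop("invalid simulation spec: duration must be >= 10 s")
  if (missing(seed)) stop("invalid simulation spec: seed is required")
  if (n_regions < 2) stop("invalid simulation spec: n_regions must be >= 2")
  bands <- canonical_bands()
  if (is.null(band_amplitudes))
    band_amplitudes <- stats::setNames(rep(1, length(bands)), names(bands))
  if (!all(names(band_amplitudes) %in% names(bands)))
    stop("invalid simulation spec: unknown band in band_amplitudes")
  if (is.null(coupling)) {
    coupling <- data.frame(i = integer(), j = integer(),
                           band = character(), kappa = numeric())
  } else {
    coupling <- as.data.frame(coupling)
    stopifnot(all(c("i", "j", "band", "kappa") %in% names(coupling)))
    if (any(coupling$kappa < 0))
      stop("invalid simulation spec: kappa must be >= 0")
    if (any(coupling$i == coupling$j))
      stop("invalid simulation spec: coupling pairs must join distinct regions")
    if (any(coupling$i > n_regions | coupling$j > n_regions | coupling$i < 1 |
            coupling$j < 1))
      stop("invalid simulation spec: coupling region index out of range")
    if (!all(coupling$band %in% names(bands)))
      stop("invalid simulation spec: unknown band in coupling")
    ## canonical pair order i < j; symmetric by construction
    swap <- coupling$i > coupling$j
    tmp <- coupling$i[swap]; coupling$i[swap] <- coupling$j[swap]
    coupling$j[swap] <- tmp
    coupling <- coupling[coupling$kappa > 0, , drop = FALSE]
    if (anyDuplicated(coupling[c("i", "j", "band")]))
      stop("invalid simulation spec: duplicate coupling entries for a pair/band")
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    stopifnot(ncol(planted_edges) == 2L)
  }
  structure(list(n_regions = as.integer(n_regions), fs = fs, duration = duration,
                 band_amplitudes = band_amplitudes, coupling = coupling,
                 noise_sd = noise_sd, planted_edges = planted_edges,
                 seed = as.integer(seed),
                 ## oscillator model constants (see the methods vignette):
                 ## bounded FM filling 90% of the band (tanh-squashed AR(1),
                 ## tau_f s), Brownian phase roughness phase_d rad^2/s, and
                 ## Gaussian-copula von Mises jitter with correlation tau_j s
                 model = list(fm_frac = 0.8, fm_gain = 1.5, tau_f = 0.4,
                              phase_d = 4, tau_j = 0.5)),
            class = "simulation_spec")
}

## ---- oscillator building blocks -------------------------------------------

## band-filling oscillator phase: carrier wanders over fm_frac of the band
## (tanh-squashed AR(1) instantaneous frequency) plus small Brownian roughness
fm_band_phase <- function(n, fs, band, model) {
  fmid <- (band$f_lo + band$f_hi) / 2
  half <- (band$f_hi - band$f_lo) / 2
  f_inst <- fmid + half * model$fm_frac * tanh(model$fm_gain * ar1_process(n, fs, model$tau_f))
  2 * pi * cumsum(f_inst) / fs + cumsum(stats::rnorm(n, 0, sqrt(model$phase_d / fs)))
}

## smooth jitter series with exact von Mises(kappa) marginal: quantile
## transform of a unit-variance AR(1) (Gaussian copula). E[exp(i theta)] is
## exactly I1(kappa)/I0(kappa).
vm_jitter <- function(n, fs, kappa, model) {
  z <- stats::pnorm(ar1_process(n, fs, model$tau_j))
  vm_quantile(kappa)(z)
}

## von Mises quantile function; wrapped-normal limit for large kappa
vm_quantile <- function(kappa, n_grid = 4096) {
  if (kappa > 50) return(function(p) stats::qnorm(p) / sqrt(kappa))
  th <- seq(-pi, pi, length.out = n_grid)
  d <- exp(kappa * (cos(th) - 1))
  cdf <- c(0, cumsum((d[-1] + d[-n_grid]) / 2))
  cdf <- cdf / cdf[n_grid]
  stats::approxfun(cdf, th, rule = 2)
}

## 1/f background: FFT-shaped white noise, power ~ 1/f, truncated below 1 Hz
onef_noise <- function(n, fs, sd_out) {
  if (sd_out <= 0) return(numeric(n))
  w <- stats::fft(stats::rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  g <- ifelse(f < 1, 0, 1 / sqrt(f))
  z <- Re(stats::fft(w * g, inverse = TRUE)) / n
  z * sd_out / stats::sd(z)
}

## coupling components per band; validates the star-shape constraint and
## returns, per band, a list of groups: list(ref, members, kappa named by member)
coupling_groups <- function(coupling, band_name, n_regions) {
  cb <- coupling[coupling$band == band_name, , drop = FALSE]
  if (nrow(cb) == 0L) return(list())
  g <- igraph::graph_from_edgelist(cbind(cb$i, cb$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_regions - igraph::vcount(g)))
  comp <- igraph::components(g)
  groups <- list()
  for (cid in which(comp$csize > 1)) {
    members <- which(comp$membership == cid)
    ref <- min(members)
    rows <- cb$i %in% members | cb$j %in% members
    sub <- cb[rows, , drop = FALSE]
    if (!all(sub$i == ref | sub$j == ref))
      stop("coupling for band ", band_name, " must form star-shaped groups: ",
           "every coupled pair in a group must include the reference region ",
           ref, " (see ?simulation_spec)")
    leaf <- ifelse(sub$i == ref, sub$j, sub$i)
    groups[[length(groups) + 1L]] <-
      list(ref = ref, members = members,
           kappa = stats::setNames(sub$kappa, leaf))
  }
  groups
}

## expected PLV table over all pairs inside coupling groups
ground_truth_plv <- function(coupling, n_regions) {
  out <- list()
  for (bn in unique(coupling$band)) {
    for (grp in coupling_groups(coupling, bn, n_regions)) {
      leaves <- as.integer(names(grp$kappa))
      r <- expected_plv(grp$kappa)
      ## reference-leaf pairs: exact Bessel ratio
      out[[length(out) + 1L]] <- data.frame(
        i = pmin(grp$ref, leaves), j = pmax(grp$ref, leaves), band = bn,
        kappa = as.numeric(grp$kappa), expected_plv = r)
      ## leaf-leaf pairs: product of ratios (independent jitters)
      if (length(leaves) > 1L) {
        cmb <- utils::combn(seq_along(leaves), 2)
        out[[length(out) + 1L]] <- data.frame(
          i = pmin(leaves[cmb[1, ]], leaves[cmb[2, ]]),
          j = pmax(leaves[cmb[1, ]], leaves[cmb[2, ]]), band = bn,
          kappa = NA_real_, expected_plv = r[cmb[1, ]] * r[cmb[2, ]])
      }
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), band = character(),
                      kappa = numeric(), expected_plv = numeric()))
  do.call(rbind, out)
}

#' Simulate phase-coupled cortical source activity
#'
#' Generates one subject's region-by-time source matrix: for each canonical
#' band every region carries a band-limited oscillation (amplitude from the
#' spec) plus a shared 1/f background. Coupled pairs share the band phase of
#' their group's reference region; non-reference members add von Mises jitter,
#' so the population PLV of each coupled pair is known in closed form and is
#' returned as ground truth.
#'
#' @param spec A [simulation_spec].
#' @return List with elements `sources` (a [source_activity]) and
#'   `ground_truth` (list: `expected_plv` data frame, `planted_edges`,
#'   `band_amplitudes`).
#' @export
simulate_coupled_sources <- function(spec) {
  if (!inherits(spec, "simulation_spec")) stop("spec must be a simulation_spec")
  n <- round(spec$fs * spec$duration)
  nr <- spec$n_regions
  bands <- canonical_bands()
  x <- matrix(0, nr, n)

  for (bn in names(bands)) {
    amp <- spec$band_amplitudes[[bn]]
    if (is.null(amp) || is.na(amp)) amp <- 0
    groups <- coupling_groups(spec$coupling, bn, nr)
    ref_of <- integer(nr)        # 0 = independent
    kappa_of <- numeric(nr)
    for (grp in groups) {
      leaves <- as.integer(names(grp$kappa))
      ref_of[leaves] <- grp$ref
      kappa_of[leaves] <- grp$kappa
      ref_of[grp$ref] <- grp$ref
    }
    if (amp == 0) next
    ## shared phases keyed by reference region so the paired design reuses them
    phase_cache <- new.env(parent = emptyenv())
    get_phase <- function(ref) {
      key <- as.character(ref)
      if (!is.null(phase_cache[[key]])) return(phase_cache[[key]])
      p <- with_seed(derive_seed(spec$seed, paste0("phase:", bn, ":", ref)),
                     fm_band_phase(n, spec$fs, bands[[bn]], spec$model))
      phase_cache[[key]] <- p
      p
    }
    for (r in seq_len(nr)) {
      if (ref_of[r] > 0 && ref_of[r] != r) {
        psi <- get_phase(ref_of[r])
        th <- with_seed(derive_seed(spec$seed, paste0("jitter:", bn, ":", r)),
                        vm_jitter(n, spec$fs, kappa_of[r], spec$model))
        x[r, ] <- x[r, ] + amp * cos(psi + th)
      } else {
        psi <- if (ref_of[r] == r) get_phase(r) else
          with_seed(derive_seed(spec$seed, paste0("phase:", bn, ":", r)),
                    fm_band_phase(n, spec$fs, bands[[bn]], spec$model))
        x[r, ] <- x[r, ] + amp * cos(psi)
      }
    }
  }
  for (r in seq_len(nr)) {
    x[r, ] <- x[r, ] + with_seed(derive_seed(spec$seed, paste0("noise:", r)),
                                 onef_noise(n, spec$fs, spec$noise_sd))
  }
  labels <- if (nr == 68) dk_region_labels() else NULL
  gt <- list(expected_plv = ground_truth_plv(spec$coupling, nr),
             planted_edges = spec$planted_edges,
             band_amplitudes = spec$band_amplitudes)
  list(sources = source_activity(x, spec$fs, labels), ground_truth = gt)
}

## ---- toy forward model ----------------------------------------------------

## deterministic Fibonacci lattice on a sphere of given radius
fibonacci_sphere <- function(m, radius = 1) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Toy spherical lead field
#'
#' Builds a sensors x sources forward gain matrix from a spherical toy
#' geometry: sensors on a unit sphere (quasi-uniform lattice with small seeded
#' jitter), sources on a concentric sphere of radius 0.8, and gain decaying
#' with the inverse square of sensor-source distance. It stands in for a
#' boundary-element forward model in simulations and tests.
#'
#' @param n_sensors Number of sensors (>= 4).
#' @param n_sources Number of sources.
#' @param seed Integer seed for the sensor jitter.
#' @return An object of class `lead_field` with elements `gain`,
#'   `sensor_labels`, `sensor_positions`, `source_positions`.
#' @export
make_toy_lead_field <- function(n_sensors, n_sources, seed = 1) {
  if (n_sensors < 4) stop("n_sensors must be >= 4")
  if (n_sources < 2) stop("n_sources must be >= 2")
  sens <- fibonacci_sphere(n_sensors, 1)
  jit <- with_seed(derive_seed(seed, "sensor-jitter"),
                   matrix(stats::rnorm(n_sensors * 3, 0, 0.02), n_sensors, 3))
  sens <- sens + jit
  sens <- sens / sqrt(rowSums(sens^2))   # back on the unit sphere
  src <- fibonacci_sphere(n_sources, 0.8)
  d2 <- outer(rowSums(sens^2), rowSums(src^2), "+") - 2 * sens %*% t(src)
  d2 <- pmax(d2, 0)
  if (any(d2 < 1e-12))
    stop("degenerate geometry: coincident sensor and source")
  gain <- 1 / d2
  ## global scalar normalization (mean column norm 1): keeps the relative
  ## depth structure but puts projected sensor series on the source scale,
  ## so microvolt-style artifact limits behave sensibly on synthetic data
  gain <- gain / mean(sqrt(colSums(gain^2)))
  if (any(colSums(abs(gain)) == 0)) stop("lead field has an all-zero column")
  structure(list(gain = gain,
                 sensor_labels = sprintf("S%03d", seq_len(n_sensors)),
                 sensor_positions = sens, source_positions = src),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d sensors x %d sources (spherical toy geometry)\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}

#' Project source activity to sensors
#'
#' Applies the forward gain matrix and adds white sensor noise:
#' `sensors = gain %*% sources + noise`.
#'
#' @param src A [source_activity] (one source per lead-field column).
#' @param lf A [make_toy_lead_field] result or compatible `lead_field`.
#' @param sensor_noise_sd White sensor noise standard deviation (default 0).
#' @param seed Optional seed for the sensor noise (default derives from 1).
#' @return A [recording] with sensor labels, positions and the source fs.
#' @export
project_to_sensors <- function(src, lf, sensor_noise_sd = 0, seed = 1) {
  stopifnot(inherits(src, "source_activity"), inherits(lf, "lead_field"))
  if (nrow(src$data) != ncol(lf$gain))
    stop("dimension mismatch: source count ", nrow(src$data),
         " does not match lead field columns ", ncol(lf$gain))
  y <- lf$gain %*% src$data
  if (sensor_noise_sd > 0) {
    y <- y + with_seed(derive_seed(seed, "sensor-noise"),
                       matrix(stats::rnorm(length(y), 0, sensor_noise_sd),
                              nrow(y), ncol(y)))
  }
  recording(y, src$fs, lf$sensor_labels, positions = lf$sensor_positions)
}

## ---- group study ----------------------------------------------------------

#' Default study specifications for the two-group, paired-condition design
#'
#' Returns the three [simulation_spec]s emulating the study conditions: a
#' control-like group with unit band amplitudes; a patient-like group with
#' elevated theta (x1.5) and reduced beta1/beta2 (x0.7) amplitudes; and a
#' planted beta2 star subnetwork (hub plus `n_planted_edges` leaves) whose
#' coupling concentration changes between the stimulation-OFF
#' (`kappa = kappa_off`) and stimulation-ON (`kappa = kappa_on`) conditions.
#'
#' @param duration Recording length per subject in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_regions Region count (default 68).
#' @param seed Master seed; OFF and ON share it so that per-subject background
#'   streams are identical and within-subject differences reflect only the
#'   planted coupling change.
#' @param theta_gain,beta_gain Patient-group amplitude factors.
#' @param kappa_off,kappa_on Planted-subnetwork coupling in the two conditions.
#' @param n_planted_edges Number of planted star edges (default 10).
#' @return List with elements `hc`, `pd_off`, `pd_on` and `planted_edges`.
#' @export
default_study_specs <- function(duration = 300, fs = 1000, n_regions = 68,
                                seed = 1, theta_gain = 1.5, beta_gain = 0.7,
                                kappa_off = 5, kappa_on = 0,
                                n_planted_edges = 10) {
  ## planted star: hub + leaves spread across the region list
  idx <- unique(round(seq(1, n_regions, length.out = n_planted_edges + 1)))
  if (length(idx) < n_planted_edges + 1)
    stop("n_regions too small for the requested planted subnetwork")
  hub <- idx[1]; leaves <- idx[-1]
  planted <- cbind(i = pmin(hub, leaves), j = pmax(hub, leaves))
  mk_coupling <- function(kappa) {
    if (kappa <= 0) return(NULL)
    data.frame(i = planted[, 1], j = planted[, 2], band = "beta2", kappa = kappa)
  }
  amp_hc <- c(theta = 1, alpha = 1, beta1 = 1, beta2 = 1)
  amp_pd <- c(theta = theta_gain, alpha = 1, beta1 = beta_gain, beta2 = beta_gain)
  list(hc = simulation_spec(n_regions, fs, duration, amp_hc,
                            seed = derive_seed(seed, "hc")),
       pd_off = simulation_spec(n_regions, fs, duration, amp_pd,
                                coupling = mk_coupling(kappa_off),
                                planted_edges = planted,
                                seed = derive_seed(seed, "pd")),
       pd_on = simulation_spec(n_regions, fs, duration, amp_pd,
                               coupling = mk_coupling(kappa_on),
                               planted_edges = planted,
                               seed = derive_seed(seed, "pd")),
       planted_edges = planted)
}

#' Simulate a two-group cohort with a paired ON/OFF condition
#'
#' Draws `n_hc` control-like subjects from `spec_hc` and `n_pd` patient-like
#' subjects in both conditions from `spec_pd_off` / `spec_pd_on`. The OFF and
#' ON specs must share the same master seed (paired design): each patient's
#' background noise and band-phase streams are then identical across
#' conditions and only the planted coupling differs.
#'
#' @param spec_hc,spec_pd_off,spec_pd_on [simulation_spec]s for the three arms.
#' @param n_hc,n_pd Group sizes (>= 2).
#' @param lead_field Optional [make_toy_lead_field]; when supplied, subjects
#'   are returned as sensor [recording]s, otherwise as source-level
#'   [source_activity].
#' @param sensor_noise_sd Sensor noise used with `lead_field`.
#' @return An object of class `cohort_study`: lists `hc`, `pd_off`, `pd_on`
#'   of per-subject data, plus `ground_truth` and the specs.
#' @export
simulate_group_study <- function(spec_hc, spec_pd_off, spec_pd_on,
                                 n_hc = 21, n_pd = 20, lead_field = NULL,
                                 sensor_noise_sd = 0.1) {
  stopifnot(inherits(spec_hc, "simulation_spec"),
            inherits(spec_pd_off, "simulation_spec"),
            inherits(spec_pd_on, "simulation_spec"))
  if (n_hc < 2 || n_pd < 2)
    stop("group sizes must be >= 2 (statistics impossible otherwise)")
  if (spec_pd_off$seed != spec_pd_on$seed)
    stop("paired design: spec_pd_off and spec_pd_on must share the same seed")
  subject_spec <- function(spec, k) {
    s <- spec
    s$seed <- derive_seed(spec$seed, paste0("subject:", k))
    s
  }
  render <- function(spec, id, group, condition) {
    sim <- simulate_coupled_sources(spec)
    out <- if (is.null(lead_field)) sim$sources else
      project_to_sensors(sim$sources, lead_field, sensor_noise_sd,
                         seed = spec$seed)
    out$meta <- list(subject = id, group = group, condition = condition,
                     seed = spec$seed)
    out
  }
  hc <- lapply(seq_len(n_hc), function(k)
    render(subject_spec(spec_hc, k), sprintf("hc%02d", k), "HC", "none"))
  pd_off <- lapply(seq_len(n_pd), function(k)
    render(subject_spec(spec_pd_off, k), sprintf("pd%02d", k), "PD", "OFF"))
  pd_on <- lapply(seq_len(n_pd), function(k)
    render(subject_spec(spec_pd_on, k), sprintf("pd%02d", k), "PD", "ON"))
  gt <- list(
    hc = simulate_ground_truth(spec_hc),
    pd_off = simulate_ground_truth(spec_pd_off),
    pd_on = simulate_ground_truth(spec_pd_on),
    ## planted amplitude-squared group power ratios (PD vs HC), per band
    expected_band_power_ratio = (spec_pd_off$band_amplitudes /
                                   spec_hc$band_amplitudes)^2)
  structure(list(hc = hc, pd_off = pd_off, pd_on = pd_on, ground_truth = gt,
                 specs = list(hc = spec_hc, pd_off = spec_pd_off,
                              pd_on = spec_pd_on)),
            class = "cohort_study")
}

simulate_ground_truth <- function(spec) {
  list(expected_plv = ground_truth_plv(spec$coupling, spec$n_regions),
       planted_edges = spec$planted_edges,
       band_amplitudes = spec$band_amplitudes)
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study> %d HC, %d PD (paired OFF/ON)\n",
              length(x$hc), length(x$pd_off)))
  invisible(x)
}
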