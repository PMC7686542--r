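## Synthetic cohorts from block-structured VAR(1) processes with known
## directed coupling. These stand in for resting-state ROI series: the
## default cohort mirrors the study design elsewhere in the package
## (27 NC vs 24 AD subjects, 52 ROIs, 190 timepoints at TR = 2 s), with
## the group contrast planted as multiplicative attenuation of all
## couplings incident to the default-network subsystems (MTL, DM, Core).

sim_defaults <- function() {
  list(within_density  = 0.30,  # P(directed edge) inside a network
       within_strength = 0.30,  # |coupling| of within-network edges
       between_density = 0.04,  # P(directed edge) across networks
       between_strength = 0.40, # |coupling| of cross-network edges
       ad_attenuation  = 0.50,  # multiplier on DN-incident couplings
       self_decay      = c(0.25, 0.45),  # AR(1) diagonal range
       noise_sd        = 1,
       spectral_cap    = 0.90)
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Build a block-structured VAR(1) coupling specification
#'
#' Constructs the lag-1 coefficient matrix `A` (entry `A[j, i]` is the
#' influence of ROI `i` at time `t-1` on ROI `j` at time `t`) for one of
#' three scenarios: `"null"` (self-decay only, no directed edges),
#' `"control"` (random block structure, denser within networks), and
#' `"ad"` (the control matrix with every coupling incident to an MTL, DM
#' or Core ROI multiplied by `ad_attenuation`). The matrix is shrunk
#' towards zero off-diagonal coupling until its spectral radius is at or
#' below the stationarity cap (0.9).
#'
#' @param partition A [network_partition()].
#' @param scenario One of `"null"`, `"control"`, `"ad"`.
#' @param params Named list overriding the generator defaults
#'   (`within_density`, `within_strength`, `between_density`,
#'   `between_strength`, `ad_attenuation`, `self_decay`, `noise_sd`).
#' @param seed Integer seed; `"control"` and `"ad"` at the same seed share
#'   the same base matrix.
#' @return An object of class `coupling_spec`: list with `A`, `noise_sd`,
#'   `label`, `partition`, and `planted` (data frame of directed edges
#'   `source`, `target`, `weight`, `dn_incident`).
#' @export
build_coupling <- function(partition, scenario = c("control", "ad", "null"),
                           params = list(), seed = 1) {
  scenario <- match.arg(scenario)
  p <- utils::modifyList(sim_defaults(), params)
  R <- n_roi(partition)
  net <- partition$network
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  A <- matrix(0, R, R, dimnames = list(partition$roi, partition$roi))
  diag(A) <- stats::runif(R, p$self_decay[1], p$self_decay[2])
  if (scenario != "null") {
    same <- outer(net, net, "==")
    off <- !diag(R)
    draw <- matrix(stats::runif(R * R), R, R)
    sign <- matrix(sample(c(-1, 1), R * R, replace = TRUE), R, R)
    A[off & same & draw < p$within_density] <-
      (p$within_strength * sign)[off & same & draw < p$within_density]
    A[off & !same & draw < p$between_density] <-
      (p$between_strength * sign)[off & !same & draw < p$between_density]
    for (k in seq_len(200)) {           # shrink coupling until stationary
      if (spectral_radius(A) <= p$spectral_cap) break
      A[off] <- A[off] * 0.95
    }
    if (spectral_radius(A) > p$spectral_cap)
      gc_abort("cannot rescale coupling to a stationary matrix", "unstable")
    if (scenario == "ad") {
      dn <- net %in% c("MTL", "DM", "Core")
      inc <- (outer(dn, rep(TRUE, R)) | outer(rep(TRUE, R), dn)) & off
      A[inc] <- A[inc] * p$ad_attenuation
    }
  }
  idx <- which(A != 0 & !diag(R), arr.ind = TRUE)   # [j = target, i = source]
  dn <- net %in% c("MTL", "DM", "Core")
  planted <- data.frame(
    source = partition$roi[idx[, 2]], target = partition$roi[idx[, 1]],
    weight = A[idx], dn_incident = dn[idx[, 1]] | dn[idx[, 2]],
    stringsAsFactors = FALSE)
  structure(list(A = A, noise_sd = rep(p$noise_sd, R), label = scenario,
                 partition = partition, planted = planted, seed = seed),
            class = "coupling_spec")
}

## save/restore the global RNG state so simulator seeds stay local
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Add or overwrite directed couplings in a coupling specification
#'
#' @param coupling A [build_coupling()] result.
#' @param pairs Data frame with `source`, `target` ROI labels.
#' @param strength Coupling weight written into each listed entry.
#' @return The modified `coupling_spec` (re-checked for stationarity).
#' @export
add_couplings <- function(coupling, pairs, strength) {
  stopifnot(inherits(coupling, "coupling_spec"))
  A <- coupling$A
  A[cbind(match(pairs$target, rownames(A)), match(pairs$source, colnames(A)))] <-
    strength
  if (spectral_radius(A) > 0.98)
    gc_abort("added couplings make the process non-stationary", "unstable")
  coupling$A <- A
  part <- coupling$partition
  idx <- which(A != 0 & !diag(nrow(A)), arr.ind = TRUE)
  dn <- part$network %in% c("MTL", "DM", "Core")
  coupling$planted <- data.frame(
    source = part$roi[idx[, 2]], target = part$roi[idx[, 1]],
    weight = A[idx], dn_incident = dn[idx[, 1]] | dn[idx[, 2]],
    stringsAsFactors = FALSE)
  coupling
}

#' Slow modulation envelope for dynamic-coupling scenarios
#'
#' A gain series `1 + amp * sin(2 pi freq t + phase) + smoothed noise`,
#' clipped to `[0.2, 1.8]`. The default frequency (0.005 Hz) is slow
#' relative to a 60-s analysis window, so windowed estimates can track
#' it; the additive noise is moving-average smoothed over 50 s so the
#' envelope's spectral content stays below 0.02 Hz.
#'
#' @param T Number of timepoints.
#' @param tr_seconds Sampling interval in seconds.
#' @param freq_hz Sinusoid frequency (Hz).
#' @param amp Sinusoid amplitude.
#' @param noise_sd Standard deviation of the smoothed noise component.
#' @param phase Phase in radians; `NULL` draws one uniformly.
#' @return Numeric vector of length `T` in `[0.2, 1.8]`.
#' @export
envelope_series <- function(T, tr_seconds = 2, freq_hz = 0.005, amp = 0.6,
                            noise_sd = 0.15, phase = NULL) {
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  t_sec <- (seq_len(T) - 1) * tr_seconds
  w <- max(3, round(50 / tr_seconds))
  raw <- stats::rnorm(T + 2 * w)
  sm <- stats::filter(raw, rep(1 / w, w), sides = 2)
  sm <- sm[w + seq_len(T)]
  sm <- sm / max(stats::sd(sm), 1e-12) * noise_sd
  pmin(1.8, pmax(0.2, 1 + amp * sin(2 * pi * freq_hz * t_sec + phase) + sm))
}

#' Simulate one subject from a VAR(1) coupling specification
#'
#' Runs the process `x_t = A_t x_{t-1} + e_t` with Gaussian innovations,
#' discards a burn-in, and returns the final `T` samples. Optional
#' `modulation` scales selected `A` entries by a per-timepoint envelope;
#' an optional `driver` adds a scaled copy of one ROI's series onto
#' target ROIs after simulation (a planted common driver for
#' partial-correlation analyses).
#'
#' @param coupling A [build_coupling()] result.
#' @param T Number of emitted timepoints (>= 30).
#' @param tr_seconds Sampling interval in seconds.
#' @param seed Integer seed (bit-reproducible output).
#' @param modulation Optional list with `sets` (list of data frames with
#'   `source`, `target`) and `envelopes` (T x n_sets matrix of gains).
#' @param driver Optional list with `source` (ROI label), `targets`
#'   (ROI labels) and `strength`.
#' @param group,subject_id Metadata for the returned record.
#' @param burn_in Burn-in samples discarded (default 200).
#' @param smooth_ma Optional moving-average window (samples): a crude
#'   stand-in for hemodynamic smoothing, off (`NULL`) by default so
#'   estimator validation is not confounded.
#' @return A [subject_record()].
#' @export
simulate_subject <- function(coupling, T = 190, tr_seconds = 2, seed = 1,
                             modulation = NULL, driver = NULL,
                             group = "NC", subject_id = "sim",
                             burn_in = 200, smooth_ma = NULL) {
  stopifnot(inherits(coupling, "coupling_spec"))
  if (T < 30) gc_abort("T must be at least 30", "too_short")
  A <- coupling$A
  if (spectral_radius(A) >= 1)
    gc_abort("non-stationary coupling (spectral radius >= 1)", "unstable")
  R <- nrow(A)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  total <- burn_in + T
  E <- matrix(stats::rnorm(total * R), total, R)
  E <- sweep(E, 2, coupling$noise_sd, "*")
  mod_idx <- NULL
  if (!is.null(modulation)) {
    env <- as.matrix(modulation$envelopes)
    if (nrow(env) != T)
      gc_abort("envelope length must equal T", "bad_modulation")
    mod_idx <- lapply(modulation$sets, function(s)
      cbind(match(s$target, rownames(A)), match(s$source, colnames(A))))
  }
  X <- matrix(0, total, R)
  x <- stats::rnorm(R) * coupling$noise_sd
  base <- A
  for (t in seq_len(total)) {
    if (!is.null(mod_idx)) {
      tt <- max(1, t - burn_in)              # envelope starts at emission
      A <- base
      for (k in seq_along(mod_idx)) A[mod_idx[[k]]] <- base[mod_idx[[k]]] * env[tt, k]
    }
    x <- as.vector(A %*% x) + E[t, ]
    X[t, ] <- x
  }
  if (max(abs(X)) > 1e8)
    gc_abort("simulated series diverged", "unstable")
  if (!is.null(smooth_ma) && smooth_ma > 1) {
    k <- as.integer(smooth_ma)
    X <- apply(X, 2, function(v)
      as.numeric(stats::filter(v, rep(1 / k, k), sides = 1)))
    X[seq_len(k - 1), ] <- X[rep(k, k - 1), ]  # pad the filter warm-up
  }
  out <- X[(burn_in + 1):total, , drop = FALSE]
  colnames(out) <- rownames(A)
  if (!is.null(driver)) {
    src <- out[, driver$source]
    for (tg in driver$targets) out[, tg] <- out[, tg] + driver$strength * src
  }
  subject_record(out, coupling$partition, subject_id, group, tr_seconds)
}

#' Simulate a two-group cohort
#'
#' Default conditions are the study design used throughout the package:
#' 27 NC and 24 AD subjects, 190 timepoints at TR = 2 s. Scenarios:
#' \describe{
#'   \item{`"ad-contrast"`}{NC subjects from the control coupling, AD
#'     subjects from the DN-attenuated coupling (same base matrix).}
#'   \item{`"null"`}{both groups from the no-coupling (diagonal) matrix.}
#'   \item{`"coevolution"`}{both groups from the control coupling with two
#'     disjoint cross-network coupling sets (FPCNA to Core, Core to DAN)
#'     modulated by slow envelopes; NC subjects share one envelope across
#'     both sets, AD subjects get independent envelopes (override with
#'     `params$shared_nc` / `params$shared_ad`).}
#' }
#' Per-subject seeds derive deterministically from `seed`. An optional
#' `params$driver = list(source, targets, strength_nc, strength_ad)`
#' plants a common driver with group-specific strength.
#'
#' @param partition A [network_partition()].
#' @param n_nc,n_ad Group sizes (defaults 27 and 24).
#' @param T Timepoints per subject (default 190).
#' @param tr_seconds Sampling interval (default 2 s).
#' @param scenario One of `"ad-contrast"`, `"null"`, `"coevolution"`.
#' @param params Generator overrides, see [build_coupling()].
#' @param seed Master integer seed.
#' @return List of [subject_record()]s with attribute `ground_truth`
#'   (couplings, planted edge list, modulation sets and envelopes).
#' @export
simulate_cohort <- function(partition, n_nc = 27, n_ad = 24, T = 190,
                            tr_seconds = 2,
                            scenario = c("ad-contrast", "null", "coevolution"),
                            params = list(), seed = 1) {
  scenario <- match.arg(scenario)
  p <- utils::modifyList(sim_defaults(), params)
  coupling_nc <- switch(scenario,
    "null" = build_coupling(partition, "null", params, seed),
    build_coupling(partition, "control", params, seed))
  coupling_ad <- switch(scenario,
    "ad-contrast" = build_coupling(partition, "ad", params, seed),
    coupling_nc)
  mod_sets <- NULL
  if (scenario == "coevolution") {
    ## build the base with spectral headroom: the envelope can scale the
    ## chain couplings up to 1.8x, and the worst-case matrix must stay
    ## stationary at every seed
    coupling_nc <- build_coupling(
      partition, "control",
      utils::modifyList(list(spectral_cap = 0.65), params), seed)
    mod_sets <- coevolution_sets(partition, params)
    for (s in mod_sets$sets) {
      coupling_nc <- add_couplings(coupling_nc, s, mod_sets$strength)
    }
    coupling_nc <- stabilize_modulated(coupling_nc, mod_sets, max_gain = 1.8)
    coupling_ad <- coupling_nc
  }
  groups <- c(rep("NC", n_nc), rep("AD", n_ad))
  ids <- sprintf("%s%02d", groups, c(seq_len(n_nc), seq_len(n_ad)))
  shared <- list(NC = isTRUE(p$shared_nc %||% TRUE),
                 AD = isTRUE(p$shared_ad %||% FALSE))
  envelopes <- vector("list", length(groups))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    subj_seed <- (seed + 104729L * i) %% 2147483647L
    coupling <- if (g == "NC") coupling_nc else coupling_ad
    modulation <- NULL
    if (!is.null(mod_sets)) {
      set.seed(subj_seed + 1L)
      n_sets <- length(mod_sets$sets)
      env <- if (shared[[g]]) {
        e <- envelope_series(T, tr_seconds)
        matrix(rep(e, n_sets), T, n_sets)
      } else {
        sapply(seq_len(n_sets), function(k) envelope_series(T, tr_seconds))
      }
      envelopes[[i]] <- env
      modulation <- list(sets = mod_sets$sets, envelopes = env)
    }
    driver <- NULL
    if (!is.null(p$driver)) {
      strength <- if (g == "NC") p$driver$strength_nc else p$driver$strength_ad
      if (!is.null(strength) && strength != 0)
        driver <- list(source = p$driver$source, targets = p$driver$targets,
                       strength = strength)
    }
    subjects[[i]] <- simulate_subject(coupling, T, tr_seconds, subj_seed,
                                      modulation, driver, g, ids[i])
  }
  names(subjects) <- ids
  attr(subjects, "ground_truth") <- list(
    scenario = scenario, coupling_nc = coupling_nc, coupling_ad = coupling_ad,
    planted = coupling_nc$planted, modulation_sets = mod_sets,
    envelopes = envelopes)
  subjects
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## shrink non-modulated off-diagonal couplings until the worst-case
## matrix (modulated entries at max envelope gain) is comfortably stable
stabilize_modulated <- function(coupling, mod_sets, max_gain = 1.8,
                                cap = 0.95) {
  A <- coupling$A
  idx <- do.call(rbind, lapply(mod_sets$sets, function(s)
    cbind(match(s$target, rownames(A)), match(s$source, colnames(A)))))
  other <- !diag(nrow(A))
  other[idx] <- FALSE
  for (k in seq_len(200)) {
    Amax <- A
    Amax[idx] <- A[idx] * max_gain
    if (spectral_radius(Amax) <= cap) break
    A[other] <- A[other] * 0.95
  }
  Amax <- A; Amax[idx] <- A[idx] * max_gain
  if (spectral_radius(Amax) > cap)
    gc_abort("cannot stabilize modulated coupling", "unstable")
  coupling$A <- A
  part <- coupling$partition
  nz <- which(A != 0 & !diag(nrow(A)), arr.ind = TRUE)
  dn <- part$network %in% c("MTL", "DM", "Core")
  coupling$planted <- data.frame(
    source = part$roi[nz[, 2]], target = part$roi[nz[, 1]],
    weight = A[nz], dn_incident = dn[nz[, 1]] | dn[nz[, 2]],
    stringsAsFactors = FALSE)
  coupling
}

## Default modulated coupling sets for the co-evolution scenario: two
## disjoint chains of cross-network edges so the windowed estimates of
## one set cannot mechanically bleed into the other.
coevolution_sets <- function(partition, params = list()) {
  p <- utils::modifyList(sim_defaults(), params)
  fp <- rois_of(partition, "FPCNA"); co <- rois_of(partition, "Core")
  da <- rois_of(partition, "DAN")
  k <- min(4, length(fp), length(co) %/% 2, length(da))
  set1 <- data.frame(source = fp[seq_len(k)], target = co[seq_len(k)],
                     stringsAsFactors = FALSE)
  set2 <- data.frame(source = co[length(co) - seq_len(k) + 1],
                     target = da[seq_len(k)], stringsAsFactors = FALSE)
  list(sets = list(FPCNA_to_Core = set1, Core_to_DAN = set2),
       strength = p$coev_strength %||% 0.35)
}
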