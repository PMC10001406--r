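#' Default maturation-scenario trajectories
#'
#' Per-session generator parameters emulating cortical culture maturation
#' on the DIV 7-21 grid: channel activation, firing rate, bursting and
#' network synchrony all rise monotonically, with identical trajectories
#' for the co- and tri-culture labels (the study conditions the maturation
#' analysis assumes).
#'
#' @return list with `grid` (DIV), and per-session vectors `pActive`,
#'   `tonicRate`, `burstOnsetRate`, `syncCopyProb`.
#' @export
maturationTrajectories <- function() {
  list(grid = c(7, 10, 14, 17, 21),
       pActive = c(0.20, 0.35, 0.50, 0.60, 0.68),
       tonicRate = c(0.20, 0.28, 0.38, 0.48, 0.60),
       burstOnsetRate = c(0.040, 0.060, 0.090, 0.120, 0.150),
       syncCopyProb = c(0.15, 0.30, 0.45, 0.60, 0.70))
}

#' Default LPS-scenario parameters
#'
#' Baseline equals the mature (DIV 21) culture; in the treated tri-culture
#' arm each channel carries an exponential death time (hazard per hour)
#' and the surviving channels' firing rates decay exponentially, emulating
#' progressive microglia-mediated silencing after LPS exposure.  Control
#' arms and the microglia-free co-culture keep baseline parameters at
#' every session.  The default hazard gives ~10\% surviving active
#' channels at 72 h.
#'
#' @return list with `grid` (hours post-exposure), `hazardPerHour`,
#'   `rateDecayPerHour`, and the baseline generator values.
#' @export
lpsParameters <- function() {
  list(grid = c(0, 3, 12, 24, 48, 72),
       hazardPerHour = 0.032,
       rateDecayPerHour = 0.040,
       pActive = 0.68, tonicRate = 0.60, burstOnsetRate = 0.150,
       syncCopyProb = 0.70)
}

#' Simulate a longitudinal multi-device MEA study
#'
#' Generates ground-truthed spike trains for every device x session of one
#' of two scenarios:
#'
#' * `"maturation"` — co- and tri-culture arms recorded at DIV
#'   7/10/14/17/21 with monotonically increasing activation, rate,
#'   bursting and synchrony (see [maturationTrajectories()]).  Channel
#'   activation is nested across sessions (channels switch on and stay
#'   on), giving each device a coherent longitudinal identity.
#' * `"lps"` — four arms (culture co/tri x condition control/lps)
#'   recorded at 0/3/12/24/48/72 h after exposure.  Only the treated
#'   tri-culture responds: persistent per-channel death plus progressive
#'   rate decay (see [lpsParameters()]).
#'
#' @param scenario `"maturation"` or `"lps"`.
#' @param nDevices devices per arm (default 8 for maturation, 4 for lps).
#' @param seed master seed; per-session generator seeds are derived from
#'   it, so the whole study is reproducible bit-for-bit.
#' @param baseConfig a [SimulationConfig-class] supplying the fixed
#'   parameters (array geometry, burst shape, noise, ...).
#' @param trajectories override of [maturationTrajectories()] /
#'   [lpsParameters()] output.
#' @return object of class `"MEAStudy"`: list with `scenario`, `grid`,
#'   `sessions` (data.frame: device, culture, condition, session, seed)
#'   and `truths` (list of [DeviceGroundTruth-class] parallel to the
#'   session rows).
#' @export
simulateStudy <- function(scenario = c("maturation", "lps"),
                          nDevices = NULL, seed = 1,
                          baseConfig = simulationConfig(),
                          trajectories = NULL) {
  scenario <- match.arg(scenario)
  # all study-level randomness (per-session seeds, channel identities,
  # death times) is drawn up front so it cannot interleave with the
  # per-device generator streams
  set.seed(seed)
  nCh <- baseConfig@nChannels
  if (scenario == "maturation") {
    tra <- trajectories %||% maturationTrajectories()
    nDevices <- nDevices %||% 8L
    arms <- expand.grid(culture = c("co", "tri"), idx = seq_len(nDevices),
                        stringsAsFactors = FALSE)
    nSess <- length(tra$grid)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                               nrow(arms) * nSess), nrow(arms), nSess)
    U <- matrix(stats::runif(nrow(arms) * nCh), nrow(arms), nCh)
    CL <- matrix(stats::runif(nrow(arms) * nCh) < baseConfig@pExcitatory,
                 nrow(arms), nCh)
    sessions <- NULL
    truths <- list()
    for (r in seq_len(nrow(arms))) {
      cu <- arms$culture[r]
      device <- sprintf("%s-%02d", cu, arms$idx[r])
      # nested activation: a channel turns on when pActive reaches its u
      u <- U[r, ]
      classDraw <- ifelse(CL[r, ], "excitatory", "inhibitory")
      for (s in seq_len(nSess)) {
        cfg <- baseConfig
        cfg@pActive <- tra$pActive[s]
        cfg@tonicRate <- tra$tonicRate[s]
        cfg@burstOnsetRate <- tra$burstOnsetRate[s]
        cfg@syncCopyProb <- tra$syncCopyProb[s]
        cfg@seed <- seeds[r, s]
        mask <- u < tra$pActive[s]
        cls <- ifelse(mask, classDraw, NA_character_)
        truths[[length(truths) + 1L]] <-
          simulateDeviceTrains(cfg, activeMask = mask, unitClass = cls)
        sessions <- rbind(sessions, data.frame(
          device = device, culture = cu, condition = "control",
          session = tra$grid[s], seed = cfg@seed,
          stringsAsFactors = FALSE))
      }
    }
  } else {
    par <- trajectories %||% lpsParameters()
    nDevices <- nDevices %||% 4L
    arms <- expand.grid(culture = c("co", "tri"),
                        condition = c("control", "lps"),
                        idx = seq_len(nDevices), stringsAsFactors = FALSE)
    nSess <- length(par$grid)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                               nrow(arms) * nSess), nrow(arms), nSess)
    U <- matrix(stats::runif(nrow(arms) * nCh), nrow(arms), nCh)
    CL <- matrix(stats::runif(nrow(arms) * nCh) < baseConfig@pExcitatory,
                 nrow(arms), nCh)
    DT <- matrix(stats::rexp(nrow(arms) * nCh,
                             max(par$hazardPerHour, 1e-12)),
                 nrow(arms), nCh)
    sessions <- NULL
    truths <- list()
    for (r in seq_len(nrow(arms))) {
      cu <- arms$culture[r]; cond <- arms$condition[r]
      device <- sprintf("%s-%s-%02d", cu, cond, arms$idx[r])
      treated <- cu == "tri" && cond == "lps"
      baseMask <- U[r, ] < par$pActive
      classDraw <- ifelse(CL[r, ], "excitatory", "inhibitory")
      deathTime <- if (treated && par$hazardPerHour > 0) DT[r, ] else
        rep(Inf, nCh)
      for (s in seq_len(nSess)) {
        h <- par$grid[s]
        cfg <- baseConfig
        cfg@pActive <- par$pActive
        cfg@tonicRate <- par$tonicRate
        cfg@burstOnsetRate <- par$burstOnsetRate
        cfg@syncCopyProb <- par$syncCopyProb
        cfg@seed <- seeds[r, s]
        scale <- if (treated) exp(-par$rateDecayPerHour * h) else 1
        mask <- baseMask & deathTime > h
        cls <- ifelse(mask, classDraw, NA_character_)
        truths[[length(truths) + 1L]] <-
          simulateDeviceTrains(cfg, activeMask = mask, unitClass = cls,
                               rateScale = scale)
        sessions <- rbind(sessions, data.frame(
          device = device, culture = cu, condition = cond,
          session = h, seed = cfg@seed, stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(scenario = scenario,
                 grid = if (scenario == "maturation")
                   (trajectories %||% maturationTrajectories())$grid
                 else (trajectories %||% lpsParameters())$grid,
                 sessions = sessions, truths = truths, seed = seed),
            class = "MEAStudy")
}

#' @export
print.MEAStudy <- function(x, ...) {
  cat(sprintf("MEAStudy (%s): %d device-sessions, %d devices, grid %s\n",
              x$scenario, nrow(x$sessions),
              length(unique(x$sessions$device)),
              paste(x$grid, collapse = "/")))
  invisible(x)
}

#' Summarize every device-session of a simulated study
#'
#' Runs the census / rate / burst / synchrony summary
#' ([summarizeSession()]) on each device-session's ground-truth trains,
#' producing the feature table consumed by [fitSplineLme()].
#'
#' @param study an `"MEAStudy"` from [simulateStudy()].
#' @param burstParams a [BurstParams-class].
#' @param synchrony logical; include the SPIKE-distance synchrony column
#'   (the costly feature — disable when only census/rate features are
#'   needed).
#' @param minSpikes census threshold.
#' @return data.frame, one row per device x session.
#' @export
summarizeStudy <- function(study, burstParams = defaultBurstParams(),
                           synchrony = TRUE, bursts = TRUE,
                           minSpikes = 10) {
  rows <- lapply(seq_len(nrow(study$sessions)), function(r) {
    meta <- as.list(study$sessions[r, c("device", "culture", "condition",
                                        "session")])
    truth <- study$truths[[r]]
    summarizeSession(truth@trains, duration = truth@config@duration,
                     burstParams = burstParams, minSpikes = minSpikes,
                     synchrony = synchrony, bursts = bursts, meta = meta)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
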