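#' Two-point power model and battery budget
#'
#' Power draw versus clock is the classic static + dynamic split
#' \eqn{P(d) = s + p_{dyn}/d}, calibrated from the two measured points:
#' full clock (divisor 1, 300 mW) and tenfold-reduced clock (divisor 10,
#' 50 mW). The battery energy defaults to the value that makes the session
#' last exactly one hour at 0% sparsity on the reduced clock — the depletion
#' experiment's calibration point.
#'
#' @param p_active_full_clock mW at the full 400 MHz clock.
#' @param p_active_reduced_clock mW at the tenfold-reduced clock.
#' @param clock_divisor the reduction factor between those two points.
#' @param p_idle mW in idle/hibernate (a free parameter of the model; must
#'   be below the reduced-clock active power).
#' @param battery_energy mJ; default `3600 * p_active_reduced_clock` so
#'   [operating_time()] at sparsity 0 is exactly 1 hour.
#' @param transmit_cost extra mJ per transmitted frame (default 0; the
#'   calibration point folds transmission into the active draw).
#' @return list of class `wce_power_model`.
#' @export
power_model <- function(p_active_full_clock = 300,
                        p_active_reduced_clock = 50,
                        clock_divisor = 10, p_idle = 10,
                        battery_energy = 3600 * p_active_reduced_clock,
                        transmit_cost = 0) {
  stopifnot(p_idle > 0, p_idle < p_active_reduced_clock,
            p_active_reduced_clock < p_active_full_clock,
            clock_divisor > 1, battery_energy > 0, transmit_cost >= 0)
  p_dyn <- (p_active_full_clock - p_active_reduced_clock) /
    (1 - 1 / clock_divisor)
  p_static <- p_active_full_clock - p_dyn
  structure(list(p_active_full_clock = p_active_full_clock,
                 p_active_reduced_clock = p_active_reduced_clock,
                 clock_divisor = clock_divisor, p_idle = p_idle,
                 battery_energy = battery_energy,
                 transmit_cost = transmit_cost,
                 p_static = p_static, p_dyn = p_dyn),
            class = "wce_power_model")
}

#' Power draw at an arbitrary clock divisor
#'
#' @param power a [power_model()].
#' @param divisor clock division factor, >= 1.
#' @return mW. Exactly reproduces the two calibration points (300 mW at 1,
#'   50 mW at 10 for the defaults).
#' @export
power_at_clock <- function(power, divisor) {
  stopifnot(inherits(power, "wce_power_model"))
  if (any(divisor < 1)) stop("clock divisor must be >= 1")
  power$p_static + power$p_dyn / divisor
}

#' Operating time versus sparsity
#'
#' Sparsity is the fraction of the session spent idle (no findings to
#' process/transmit): \eqn{T(\sigma) = E / (\sigma p_{idle} + (1-\sigma)
#' p_{active})} with the reduced-clock active power. Strictly increasing and
#' continuous in sparsity; at the default calibration T(0) = 1 hour.
#'
#' @param power a [power_model()].
#' @param sparsity value(s) in \[0, 1\].
#' @return hours.
#' @export
operating_time <- function(power, sparsity) {
  stopifnot(inherits(power, "wce_power_model"),
            all(sparsity >= 0), all(sparsity <= 1))
  draw <- sparsity * power$p_idle + (1 - sparsity) * power$p_active_reduced_clock
  (power$battery_energy / draw) / 3600
}

#' Sparsity needed to reach a target operating time
#'
#' Closed-form inverse of [operating_time()]; `NA` when the target exceeds
#' the idle-limited maximum `E / p_idle`.
#'
#' @param power a [power_model()].
#' @param hours target operating time.
#' @return sparsity in \[0, 1\], or NA if unattainable.
#' @export
sparsity_for_hours <- function(power, hours) {
  need <- power$battery_energy / (hours * 3600)
  s <- (power$p_active_reduced_clock - need) /
    (power$p_active_reduced_clock - power$p_idle)
  ifelse(s >= 0 & s <= 1, s, NA_real_)
}

#' Initial capsule state
#'
#' @param power a [power_model()]; the state starts with its full battery.
#' @param frame_rate_decay consecutive insignificant frames after which the
#'   frame rate falls back to 1 fps.
#' @param transmit_every localization cadence: every Nth consecutive
#'   insignificant frame is transmitted instead of deleted (the counter
#'   resets on a significant frame).
#' @return list of class `wce_capsule_state`.
#' @export
capsule_state <- function(power = power_model(), frame_rate_decay = 10L,
                          transmit_every = 5L) {
  structure(list(mode = "active", frame_rate = 1L, modality = "WLI",
                 frames_seen = 0L, insignificant_streak = 0L,
                 transmitted = integer(), deleted = integer(),
                 energy_remaining = power$battery_energy,
                 network_version = "initial", pending_nbi = FALSE,
                 frame_rate_decay = as.integer(frame_rate_decay),
                 transmit_every = as.integer(transmit_every),
                 power = power),
            class = "wce_capsule_state")
}

#' Switch the capsule between active and hibernate modes
#'
#' Hibernation is triggered externally (in the real device by anatomical
#' landmark recognition, which is out of scope here): a hibernating capsule
#' draws idle power and neither transmits nor deletes frames.
#'
#' @param state a `wce_capsule_state`.
#' @param mode `"active"` or `"hibernate"`.
#' @return the updated state.
#' @export
set_capsule_mode <- function(state, mode) {
  stopifnot(inherits(state, "wce_capsule_state"))
  state$mode <- match.arg(mode, c("active", "hibernate"))
  state
}

#' Advance the capsule one frame
#'
#' Embodies the onboard transmission policy: a significant frame (at least
#' one confidence-filtered detection) is always transmitted, raises the
#' frame rate to 2 fps and schedules an NBI capture of the same scene; an
#' insignificant frame is deleted except that every Nth consecutive one is
#' transmitted for localization. After a run of insignificant frames the
#' rate decays back to 1 fps. Each frame costs active power for its capture
#' interval; the session ends when the battery empties.
#'
#' @param state a `wce_capsule_state`.
#' @param frame_id identifier of the processed frame.
#' @param detections confidence-filtered box data.frame for the frame.
#' @return list(state, action) where action has `decision`
#'   ("transmit"/"delete"), `significant`, `capture_nbi_next`, `energy_used`,
#'   `session_over`.
#' @export
capsule_step <- function(state, frame_id, detections) {
  stopifnot(inherits(state, "wce_capsule_state"))
  if (state$energy_remaining <= 0)
    return(list(state = state,
                action = list(decision = "none", significant = NA,
                              capture_nbi_next = FALSE, energy_used = 0,
                              session_over = TRUE)))
  if (state$mode == "hibernate") {
    energy <- min(state$power$p_idle, state$energy_remaining)
    state$energy_remaining <- state$energy_remaining - energy
    return(list(state = state,
                action = list(decision = "none", significant = NA,
                              capture_nbi_next = FALSE, energy_used = energy,
                              session_over = state$energy_remaining <= 0)))
  }
  significant <- classify_frame(detections) == "significant"
  dwell <- 1 / state$frame_rate # seconds at the current rate
  energy <- state$power$p_active_reduced_clock * dwell
  state$frames_seen <- state$frames_seen + 1L
  capture_nbi <- FALSE
  if (significant) {
    decision <- "transmit"
    state$transmitted <- c(state$transmitted, frame_id)
    state$insignificant_streak <- 0L
    state$frame_rate <- 2L
    capture_nbi <- state$modality == "WLI"
    state$pending_nbi <- capture_nbi
    energy <- energy + state$power$transmit_cost
  } else {
    state$insignificant_streak <- state$insignificant_streak + 1L
    if (state$insignificant_streak %% state$transmit_every == 0L) {
      decision <- "transmit"
      state$transmitted <- c(state$transmitted, frame_id)
      energy <- energy + state$power$transmit_cost
    } else {
      decision <- "delete"
      state$deleted <- c(state$deleted, frame_id)
    }
    if (state$insignificant_streak >= state$frame_rate_decay)
      state$frame_rate <- 1L
    state$pending_nbi <- FALSE
  }
  energy <- min(energy, state$energy_remaining)
  state$energy_remaining <- state$energy_remaining - energy
  list(state = state,
       action = list(decision = decision, significant = significant,
                     capture_nbi_next = capture_nbi, energy_used = energy,
                     session_over = state$energy_remaining <= 0))
}

#' Replace the onboard network over the air
#'
#' The mid-session reprogramming path: the incoming network must match the
#' deployed architecture contract (same spec hash); otherwise it is rejected
#' and the session continues on the old weights. Counters and the energy
#' ledger are untouched either way.
#'
#' @param state a `wce_capsule_state` (or a session in progress).
#' @param current_network the deployed `wce_network`.
#' @param new_network the uploaded replacement.
#' @return list(network, state, accepted).
#' @export
otap_update <- function(state, current_network, new_network) {
  if (!inherits(new_network, "wce_network") ||
      !identical(new_network$spec_hash, current_network$spec_hash)) {
    return(list(network = current_network, state = state, accepted = FALSE))
  }
  state$network_version <- new_network$version
  list(network = new_network, state = state, accepted = TRUE)
}

#' Run a full capsule session
#'
#' Streams frames through the onboard pipeline — forward, grid decode,
#' confidence filter, NMS, frame classification, transmission policy — until
#' the stream or the battery is exhausted. When a significant WLI frame
#' schedules an NBI capture, the same scene is re-captured under NBI
#' ([render_nbi()]) and processed as the next frame. Deterministic for fixed
#' inputs.
#'
#' @param frames list of WLI `wce_frame`.
#' @param network a `wce_network`.
#' @param config a [head_config()].
#' @param state0 initial [capsule_state()].
#' @param otap_at optional list(frame = i, network = net): after processing
#'   frame i, attempt an over-the-air swap to `net`.
#' @return list of class `wce_session`: `log` (one row per processed
#'   capture), `state` (final), `network` (possibly swapped).
#' @export
run_session <- function(frames, network, config = head_config(),
                        state0 = capsule_state(), otap_at = NULL) {
  stopifnot(length(frames) > 0)
  state <- state0
  log <- list()
  li <- 0L
  for (i in seq_along(frames)) {
    queue <- list(frames[[i]])
    fid_base <- i
    sub <- 0L
    while (length(queue) > 0) {
      fr <- queue[[1]]; queue <- queue[-1]
      fid <- fid_base + sub / 10 # x.1 marks the NBI recapture of scene x
      dets <- detect_polyps(network, fr$pixels, config)
      res <- capsule_step(state, fid, dets)
      state <- res$state
      li <- li + 1L
      log[[li]] <- data.frame(
        frame_id = fid, scene = i, modality = fr$modality,
        n_detections = nrow(dets),
        significant = isTRUE(res$action$significant),
        decision = res$action$decision, frame_rate = state$frame_rate,
        energy_used = res$action$energy_used,
        energy_remaining = state$energy_remaining,
        network_version = state$network_version)
      if (res$action$session_over) {
        return(finish_session(log, state, network))
      }
      if (res$action$capture_nbi_next && fr$modality == "WLI") {
        sub <- sub + 1L
        queue <- c(list(render_nbi(fr)), queue)
      }
    }
    if (!is.null(otap_at) && i == otap_at$frame) {
      sw <- otap_update(state, network, otap_at$network)
      network <- sw$network; state <- sw$state
    }
  }
  finish_session(log, state, network)
}

finish_session <- function(log, state, network) {
  structure(list(log = do.call(rbind, log), state = state, network = network),
            class = "wce_session")
}

#' @export
print.wce_session <- function(x, ...) {
  lg <- x$log
  cat("<wce_session> ", nrow(lg), " captures: ",
      sum(lg$decision == "transmit"), " transmitted, ",
      sum(lg$decision == "delete"), " deleted; energy ",
      sprintf("%.0f", x$state$energy_remaining), " mJ remaining\n", sep = "")
  invisible(x)
}
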