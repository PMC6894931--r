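#' Default pressure-channel levels (mbar)
#'
#' LOW (+20 mbar) keeps solution flowing out of an idle tip, HIGH (+70 mbar)
#' protects the tip while moving through the slice, PATCH is the
#' operator-variable sealing suction, ATMOSPHERE (0) holds an established
#' whole-cell recording, and CLEAN alternates -350 mbar suction with
#' +1000 mbar (1 bar) expulsion during the detergent wash.
#'
#' @return named numeric vector of channel levels; the CLEAN entry is the
#'   suction level (the schedule itself alternates suction and expulsion).
#' @export
defaultChannels <- function() {
  c(LOW = 20, HIGH = 70, PATCH = NA_real_, ATMOSPHERE = 0, CLEAN = -350)
}

# Default valve routing table: three two-position solenoid valves in a tree.
# The root valve selects the positive-pressure branch (A) or the
# atmosphere/clean branch (B); each branch valve selects one of its two
# sources. HIGH and PATCH share one output upstream of the tree, so the tree
# routes four sources. Branch valves on the inactive branch are held at 0
# (canonical form), making source -> valve-state a bijection.
.defaultValveTable <- function() {
  data.frame(
    source  = c("LOW", "HIGH/PATCH", "ATMOSPHERE", "CLEAN"),
    root    = c(0L, 0L, 1L, 1L),
    branchA = c(0L, 1L, 0L, 0L),
    branchB = c(0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
}

#' Create a virtual pressure rig
#'
#' A discrete-event model of the pneumatic controller: one three-valve tree
#' per pipette routing exactly one of four sources (LOW, HIGH/PATCH,
#' ATMOSPHERE, CLEAN), a patching-phase state machine, and the timed
#' cleaning schedule. State is carried functionally: every operation
#' returns an updated rig.
#'
#' @param n_pipettes number of pipettes (1..10).
#' @param channels named channel levels in mbar (see
#'   \code{\link{defaultChannels}}).
#' @param patch_mbar scripted pressure for the operator-variable PATCH
#'   channel (mbar).
#' @return a list-based rig object (class \code{"pressureRig"}).
#' @examples
#' rig <- pressureRig(8)
#' rig <- setChannel(rig, 1, "LOW")
#' pipetteState(rig)[1, ]
#' @export
pressureRig <- function(n_pipettes, channels = defaultChannels(),
                        patch_mbar = -15) {
  stopifnot(n_pipettes >= 1, n_pipettes <= 10)
  if (channels[["LOW"]] <= 0 || channels[["HIGH"]] <= 0)
    stop("LOW and HIGH must be strictly positive", call. = FALSE)
  if (channels[["CLEAN"]] >= 0)
    stop("CLEAN suction must be strictly negative", call. = FALSE)
  channels[["PATCH"]] <- patch_mbar
  structure(list(
    n_pipettes = as.integer(n_pipettes),
    channels = channels,
    valve_table = .defaultValveTable(),
    state = data.frame(
      id = seq_len(n_pipettes),
      phase = "staged",
      channel = "LOW",
      root = 0L, branchA = 0L, branchB = 0L,
      stringsAsFactors = FALSE),
    clock = 0,
    events = .emptyEvents()
  ), class = "pressureRig")
}

.emptyEvents <- function() {
  data.frame(timestamp = numeric(0), pipette = integer(0),
             kind = character(0), payload = character(0),
             stringsAsFactors = FALSE)
}

.logEvent <- function(rig, pipette, kind, payload, t = rig$clock) {
  rig$events <- rbind(rig$events, data.frame(
    timestamp = t, pipette = as.integer(pipette), kind = kind,
    payload = payload, stringsAsFactors = FALSE))
  rig
}

#' @rdname pressureRig
#' @param rig a rig from \code{\link{pressureRig}}.
#' @export
pipetteState <- function(rig) rig$state

#' @rdname pressureRig
#' @export
rigEvents <- function(rig) rig$events

#' @export
print.pressureRig <- function(x, ...) {
  cat(sprintf("pressureRig: %d pipettes, clock %.2f s, %d events\n",
              x$n_pipettes, x$clock, nrow(x$events)))
  print(x$state[, c("id", "phase", "channel")])
  invisible(x)
}

#' Route a pressure channel to a pipette
#'
#' Sets the three valves of the pipette's tree to the unique configuration
#' routing the requested channel; idempotent; emits a channel-switch event.
#'
#' @param rig a rig from \code{\link{pressureRig}}.
#' @param pipette pipette id.
#' @param channel one of \code{"LOW"}, \code{"HIGH"}, \code{"PATCH"},
#'   \code{"ATMOSPHERE"}, \code{"CLEAN"}.
#' @return the updated rig.
#' @export
setChannel <- function(rig, pipette, channel) {
  if (!pipette %in% rig$state$id) stop("unknown pipette", call. = FALSE)
  if (!channel %in% names(rig$channels))
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  src <- if (channel %in% c("HIGH", "PATCH")) "HIGH/PATCH" else channel
  row <- rig$valve_table[rig$valve_table$source == src, ]
  i <- match(pipette, rig$state$id)
  rig$state$channel[i] <- channel
  rig$state[i, c("root", "branchA", "branchB")] <-
    row[, c("root", "branchA", "branchB")]
  .logEvent(rig, pipette, "channel-switch", channel)
}

#' Pressure currently applied to a pipette (mbar)
#'
#' @param rig a rig.
#' @param pipette pipette id.
#' @return pressure in mbar; for CLEAN, the suction level (the schedule
#'   alternates suction/expulsion).
#' @export
channelPressure <- function(rig, pipette) {
  i <- match(pipette, rig$state$id)
  unname(rig$channels[[rig$state$channel[i]]])
}

# Legal phase transitions of the patching state machine.
.phaseNext <- list(staged = "approaching", approaching = "sealing",
                   sealing = c("whole_cell", "failed"),
                   failed = "staged", whole_cell = character(0))

.phaseChannel <- c(staged = "LOW", approaching = "HIGH", sealing = "PATCH",
                   whole_cell = "ATMOSPHERE", failed = "ATMOSPHERE")

#' Advance a pipette's patching phase
#'
#' Phases follow staged -> approaching -> sealing -> whole_cell | failed;
#' a failed pipette returns to staged after cleaning. Each phase mandates a
#' pressure channel: LOW while staged, HIGH while approaching through the
#' slice, the operator-controlled PATCH suction while sealing, ATMOSPHERE
#' once whole-cell. Illegal jumps raise a protocol violation.
#'
#' @param rig a rig.
#' @param pipette pipette id.
#' @param phase requested phase.
#' @return the updated rig (channel switched to the mandated one).
#' @export
patchPhaseAdvance <- function(rig, pipette, phase) {
  i <- match(pipette, rig$state$id)
  if (is.na(i)) stop("unknown pipette", call. = FALSE)
  cur <- rig$state$phase[i]
  if (!phase %in% .phaseNext[[cur]])
    stop(sprintf("protocol-violation: %s -> %s is not a legal transition",
                 cur, phase), call. = FALSE)
  rig$state$phase[i] <- phase
  rig <- setChannel(rig, pipette, .phaseChannel[[phase]])
  .logEvent(rig, pipette, "phase-advance", phase)
}

#' The timed pipette-cleaning pressure schedule
#'
#' Five cycles of suction (-350 mbar, 1 s) and expulsion (+1000 mbar, 1 s)
#' with the tip in the detergent well, a long expulsion (+1000 mbar, 10 s)
#' in the detergent well, then a final expulsion (+1000 mbar, 10 s) at the
#' rim of the recording well: 12 steps, 30 s of active pressure.
#'
#' @return data.frame of steps: \code{pressure_mbar}, \code{duration_s},
#'   \code{location}.
#' @examples
#' sched <- cleaningSchedule()
#' nrow(sched)                 # 12
#' sum(sched$duration_s)       # 30
#' @export
cleaningSchedule <- function() {
  cyc <- data.frame(
    pressure_mbar = rep(c(-350, 1000), 5L),
    duration_s = rep(1, 10L),
    location = "cleaning_well",
    stringsAsFactors = FALSE)
  rbind(cyc,
        data.frame(pressure_mbar = 1000, duration_s = 10,
                   location = "cleaning_well", stringsAsFactors = FALSE),
        data.frame(pressure_mbar = 1000, duration_s = 10,
                   location = "recording_well_rim", stringsAsFactors = FALSE))
}

#' Run the cleaning sequence on selected pipettes
#'
#' Simulates, concurrently for all selected pipettes: retraction above the
#' slice, travel to the detergent well, the \code{\link{cleaningSchedule}},
#' the rim expulsion, and return above the slice. Pipettes holding cells
#' (whole_cell phase) must not be selected and are never touched. Cleaned
#' pipettes end on the LOW channel above the slice; failed pipettes return
#' to the staged phase.
#'
#' @param rig a rig.
#' @param pipettes integer ids to clean.
#' @param move_speed manipulator speed, um/s.
#' @param legs_um named numeric of movement-leg lengths (um):
#'   \code{retract}, \code{to_well}, \code{to_rim}, \code{return}.
#' @return the updated rig; the event log gains move and step events, all
#'   timestamps non-decreasing per pipette.
#' @export
runCleaning <- function(rig, pipettes, move_speed = 2000,
                        legs_um = c(retract = 2000, to_well = 20000,
                                    to_rim = 15000, return = 18000)) {
  idx <- match(pipettes, rig$state$id)
  if (anyNA(idx)) stop("unknown pipette", call. = FALSE)
  if (any(rig$state$phase[idx] == "whole_cell"))
    stop("protocol-violation: cannot clean a pipette holding a cell",
         call. = FALSE)
  sched <- cleaningSchedule()
  t0 <- rig$clock
  for (p in pipettes) {
    t <- t0
    rig <- .logEvent(rig, p, "move-start", "retract", t)
    t <- t + legs_um[["retract"]] / move_speed
    rig <- .logEvent(rig, p, "move-end", "retract", t)
    rig <- setChannel(rig, p, "CLEAN")
    rig$events$timestamp[nrow(rig$events)] <- t
    rig <- .logEvent(rig, p, "move-start", "to_well", t)
    t <- t + legs_um[["to_well"]] / move_speed
    rig <- .logEvent(rig, p, "move-end", "to_well", t)
    for (k in seq_len(nrow(sched))) {
      if (sched$location[k] == "recording_well_rim" &&
          sched$location[k - 1L] == "cleaning_well") {
        rig <- .logEvent(rig, p, "move-start", "to_rim", t)
        t <- t + legs_um[["to_rim"]] / move_speed
        rig <- .logEvent(rig, p, "move-end", "to_rim", t)
      }
      rig <- .logEvent(rig, p, "step-start",
                       sprintf("%+g mbar @ %s", sched$pressure_mbar[k],
                               sched$location[k]), t)
      t <- t + sched$duration_s[k]
      rig <- .logEvent(rig, p, "step-end",
                       sprintf("%+g mbar", sched$pressure_mbar[k]), t)
    }
    rig <- .logEvent(rig, p, "move-start", "return", t)
    t <- t + legs_um[["return"]] / move_speed
    rig <- .logEvent(rig, p, "move-end", "return", t)
    rig <- setChannel(rig, p, "LOW")
    rig$events$timestamp[nrow(rig$events)] <- t
    i <- match(p, rig$state$id)
    if (rig$state$phase[i] == "failed") rig$state$phase[i] <- "staged"
  }
  # concurrent: all selected pipettes share the same wall-clock span
  rig$clock <- t0 + sum(legs_um) / move_speed + sum(sched$duration_s)
  rig
}

#' Linear-alkylbenzene-sulfonate concentration after pipette cleaning
#'
#' Mass balance for detergent carried into the recording bath on the outside
#' of a cleaned pipette tip: the LAS concentration (percent w/v) reached in
#' the bath when a volume of Alconox solution adheres to the tip.
#'
#' @param adherent_volume_ul Alconox solution adhering to the tip (ul).
#' @param bath_volume_ul recording bath volume (ul, default 1000 = 1 ml).
#' @param alconox_frac Alconox mass fraction of the cleaning solution
#'   (default 0.02 = 2 percent).
#' @param las_frac_of_alconox LAS fraction of Alconox (default 0.2).
#' @return LAS concentration in percent; glycine-receptor interference is
#'   reported at 0.001 percent.
#' @examples
#' lasConcentration(0.2)   # ~8e-5 %, well under the 0.001 % threshold
#' @export
lasConcentration <- function(adherent_volume_ul, bath_volume_ul = 1000,
                             alconox_frac = 0.02, las_frac_of_alconox = 0.2) {
  stopifnot(adherent_volume_ul >= 0, bath_volume_ul > 0,
            alconox_frac >= 0, alconox_frac <= 1,
            las_frac_of_alconox >= 0, las_frac_of_alconox <= 1)
  100 * (adherent_volume_ul * alconox_frac * las_frac_of_alconox) /
    (bath_volume_ul + adherent_volume_ul)
}
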