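#' Construct a self-organizing fuzzy logic controller
#'
#' Builds the 4-input/2-output SOFLC: four input linguistic variables
#' (error and integral error of muscle relaxation and of blood pressure,
#' each scaled to a `[-1, 1]` universe with seven triangular labels
#' NB..PB) decomposed into six two-input subsystems; one rule-base per
#' output channel (atracurium increment, isoflurane increment) spanning
#' the six pairs; Mamdani min-max inference; Karnik-Mendel type
#' reduction; and the performance-index self-organizing layer that
#' shifts or creates rules online. The three `kind`s share one engine:
#' `"type1"` uses zero FOU width and one slice, `"interval_t2"` one slice
#' with the configured FOU width, `"zslice_t2"` a stack of `n_zslices`
#' nested slices.
#'
#' Error sign conventions make a positive error always mean "more drug
#' needed": the muscle-relaxation error is set point minus measurement,
#' the blood-pressure error is measurement minus set point (isoflurane
#' lowers MAP). Output labels ZE..PB sit at peaks 0, 1/3, 2/3, 1 of the
#' increment universe, so the defuzzified increments are nonnegative and
#' drug signals only rise or hold; see the vignette for the consequences.
#'
#' @param kind controller variant.
#' @param rulebases list with elements `atracurium` and `isoflurane`
#'   ([rulebase()] objects), or a kind string accepted by
#'   [default_rulebases()].
#' @param gains a [control_gains()] object.
#' @param fou_width FOU width for the type-2 kinds: a half-width in
#'   universe units for the `"inner"`/`"feet"` styles (default 0.1, i.e.
#'   5% of the input universe span), a membership-height fraction for
#'   `"height"`.
#' @param fou_style FOU geometry, see [build_partition()]. The `"inner"`
#'   style (upper membership function = the type-1 triangle, lower foot
#'   pulled in) is the controller default: blurring the feet outward
#'   (`"feet"`) extends each set's support, and with the nonnegative
#'   output vocabulary those remote weak firings give the type-2
#'   controllers a systematic overdosing bias near equilibrium; the
#'   uniform `"height"` style at the other extreme collapses the
#'   Karnik-Mendel midpoint onto the type-1 centroid, erasing the
#'   distinction between the kinds.
#' @param n_zslices number of zSlices for the `"zslice_t2"` kind.
#' @param ctrl_period controller sampling period, minutes.
#' @param n_grid output-grid resolution for truncation and centroids.
#' @param self_organize enable the rule-modification layer.
#' @param combine how the six subsystem outputs merge into a channel
#'   increment: `"weighted"` (default) weights each subsystem's
#'   defuzzified output by its maximal firing strength, so weakly fired
#'   subsystems cannot dominate; `"mean"` is the unweighted mean.
#' @param blame which rules of a subsystem receive a correction:
#'   `"all"` (default) shifts every rule fired at the responsible step,
#'   `"max"` only the maximally-firing one.
#' @return an environment of class `"soflc_controller"`.
#' @export
soflc_controller <- function(kind = c("type1", "interval_t2", "zslice_t2"),
                             rulebases = "expert",
                             gains = control_gains(),
                             fou_width = 0.1,
                             fou_style = c("inner", "feet", "height"),
                             n_zslices = 5L,
                             ctrl_period = 1,
                             n_grid = 1001L,
                             self_organize = TRUE,
                             combine = c("weighted", "mean"),
                             blame = c("all", "max")) {
  kind <- match.arg(kind)
  combine <- match.arg(combine)
  blame <- match.arg(blame)
  fou_style <- match.arg(fou_style)
  if (is.character(rulebases)) rulebases <- default_rulebases(rulebases)
  stopifnot(is.list(rulebases),
            inherits(rulebases$atracurium, "rulebase"),
            inherits(rulebases$isoflurane, "rulebase"))
  fw <- switch(kind, type1 = 0, fou_width)
  nz <- switch(kind, zslice_t2 = as.integer(n_zslices), 1L)
  ctrl <- new.env(parent = emptyenv())
  ctrl$kind <- kind
  ctrl$gains <- gains
  ctrl$combine <- combine
  ctrl$blame <- blame
  ctrl$ctrl_period <- ctrl_period
  ctrl$in_part <- build_partition("input", c(-1, 1), input_labels(),
                                  fou_width = fw, n_zslices = nz,
                                  fou_style = fou_style)
  # output command levels: ZE..PB peaks at 0, 1/3, 2/3, 1
  ctrl$out_part <- build_partition("command", c(0, 1), output_labels(),
                                   fou_width = fw, n_zslices = nz,
                                   fou_style = fou_style)
  ctrl$cons <- consequent_grid(ctrl$out_part, n_grid)
  ctrl$pim <- pi_matrix()
  ctrl$channels <- c("atracurium", "isoflurane")
  ctrl$rb <- list(atracurium = rb_to_matrices(rulebases$atracurium),
                  isoflurane = rb_to_matrices(rulebases$isoflurane))
  ctrl$fires <- list(atracurium = replicate(6, matrix(0L, 7, 7),
                                            simplify = FALSE),
                     isoflurane = replicate(6, matrix(0L, 7, 7),
                                            simplify = FALSE))
  ctrl$totals <- list(atracurium = integer(6), isoflurane = integer(6))
  # credit-assignment delay in controller steps, per channel dead time
  ctrl$delay <- c(atracurium = as.integer(round(1 / ctrl_period)),
                  isoflurane = as.integer(round(0.42 / ctrl_period)))
  hist_len <- max(ctrl$delay) + 1L
  ctrl$history <- list(atracurium = vector("list", hist_len),
                       isoflurane = vector("list", hist_len))
  ctrl$step <- 0L
  ctrl$ie <- c(mr = 0, bp = 0)
  ctrl$self_organize <- isTRUE(self_organize)
  ctrl$n_added <- 0L
  ctrl$change_log <- list()
  class(ctrl) <- c("soflc_controller", class(ctrl))
  ctrl
}

#' Controller gain schedule
#'
#' Scale factors mapping physical signals to fuzzy universes and the
#' fuzzy output to drug units. Errors are divided by their reference
#' ranges (`e_mr_ref` normalized paralysis units, `e_bp_ref` mmHg) and
#' clamped to `[-1, 1]`; integral errors accumulate in raw units x
#' minutes, leaking with time constant `ie_leak` (minutes, `Inf` = pure
#' integral), and are divided by `ie_mr_ref` / `ie_bp_ref`.
#'
#' The defuzzified output of a channel (in `[0, 1]`, the label ZE
#' meaning "no drug" and PB "full-scale drug") is interpreted as the
#' commanded drug level: `out_mr` and `out_bp` are the full-scale drug
#' amounts (normalized atracurium infusion units; percent isoflurane),
#' and each controller step changes the drug signal by
#' `track * (command - current) * dt` -- the change of the infusion
#' rate/concentration, integrated into the (nonnegative) drug signal.
#' The change is negative whenever the commanded level is below the
#' current one, which is how the controller backs off after overshoot.
#'
#' @param e_mr_ref,e_bp_ref error scaling references.
#' @param ie_mr_ref,ie_bp_ref integral-error scaling references.
#' @param out_mr,out_bp full-scale drug levels commanded by a PB output.
#' @param track_mr,track_bp tracking rates (fraction of the
#'   command-minus-current gap applied per minute).
#' @param ie_leak integral leak time constant, minutes.
#' @return an object of class `"control_gains"`.
#' @export
control_gains <- function(e_mr_ref = 0.1, e_bp_ref = 15,
                          ie_mr_ref = 20, ie_bp_ref = 2000,
                          out_mr = 1.5, out_bp = 3,
                          track_mr = 0.03, track_bp = 0.05,
                          ie_leak = 20) {
  stopifnot(e_mr_ref > 0, e_bp_ref > 0, ie_mr_ref > 0, ie_bp_ref > 0,
            out_mr >= 0, out_bp >= 0, track_mr > 0, track_bp > 0,
            ie_leak > 0)
  structure(list(e_mr_ref = e_mr_ref, e_bp_ref = e_bp_ref,
                 ie_mr_ref = ie_mr_ref, ie_bp_ref = ie_bp_ref,
                 out_mr = out_mr, out_bp = out_bp,
                 track_mr = track_mr, track_bp = track_bp,
                 ie_leak = ie_leak),
            class = "control_gains")
}

clamp1 <- function(x) min(1, max(-1, x))

# inference for one decomposed pair of one channel.
# M1, M2: membership arrays (7, nslice, 2); rules: 7x7 integer matrix.
# returns list(crisp, fired (matrix cells), fmax_cell or NULL)
pair_inference <- function(ctrl, rules, M1, M2) {
  ns <- dim(M1)[2L]
  cand1 <- which(M1[, 1L, 2L] > 0)
  cand2 <- which(M2[, 1L, 2L] > 0)
  fired <- NULL
  fl <- list(); cons <- integer(0)
  fmax <- -1; fmax_cell <- NULL
  for (i in cand1) for (j in cand2) {
    ci <- rules[i, j]
    if (ci == 0L) next
    f <- cbind(pmin(M1[i, , 1L], M2[j, , 1L]),
               pmin(M1[i, , 2L], M2[j, , 2L]))
    if (f[1L, 2L] <= 0) next
    fired <- rbind(fired, c(i, j))
    fl[[length(fl) + 1L]] <- f
    cons <- c(cons, ci)
    if (f[1L, 2L] > fmax) { fmax <- f[1L, 2L]; fmax_cell <- c(i, j) }
  }
  if (length(cons) == 0L)
    return(list(crisp = NA_real_, fired = NULL, fmax_cell = NULL))
  ngrid <- length(ctrl$cons$grid)
  cz <- ctrl$out_part$z
  cent <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    up <- numeric(ngrid); lo <- numeric(ngrid)
    for (r in seq_along(cons)) {
      f <- fl[[r]]
      up <- pmax(up, pmin(f[s, 2L], ctrl$cons$up[cons[r], s, ]))
      lo <- pmax(lo, pmin(f[s, 1L], ctrl$cons$lo[cons[r], s, ]))
    }
    if (all(up <= 0)) next
    cent[s] <- (km_bound(ctrl$cons$grid, up, lo, TRUE) +
                  km_bound(ctrl$cons$grid, up, lo, FALSE)) / 2
  }
  keep <- !is.na(cent)
  crisp <- if (any(keep)) sum(cz[keep] * cent[keep]) / sum(cz[keep])
           else NA_real_
  list(crisp = crisp, fired = fired, fmax_cell = fmax_cell, fmax = fmax)
}

#' Advance the controller by one sampling step
#'
#' Fuzzifies the scaled errors, runs the six decomposed subsystems for
#' both output channels (the channel increment is the mean of the
#' defuzzified outputs of the subsystems in which at least one rule
#' fired), updates firing statistics, and -- when self-organization is
#' enabled -- applies the performance-index correction to the rules fired
#' at the credit-assignment step, creating rules where none fired.
#'
#' @param ctrl a [soflc_controller()].
#' @param meas_mr,meas_bp measured paralysis (0-1) and MAP (mmHg).
#' @param set_mr,set_bp current set points.
#' @param u1,u2 current drug signals (used by the level-tracking output
#'   stage; see [control_gains()]).
#' @return list with `du1`, `du2` (signed drug changes for one controller
#'   period), `n_fired`, `n_added`.
#' @export
controller_step <- function(ctrl, meas_mr, meas_bp, set_mr, set_bp,
                            u1 = 0, u2 = 0) {
  stopifnot(inherits(ctrl, "soflc_controller"))
  g <- ctrl$gains
  dt <- ctrl$ctrl_period
  e_mr <- set_mr - meas_mr
  e_bp <- meas_bp - set_bp
  leak <- if (is.finite(g$ie_leak)) exp(-dt / g$ie_leak) else 1
  ctrl$ie <- ctrl$ie * leak + c(e_mr, e_bp) * dt
  x <- c(E_MR = clamp1(e_mr / g$e_mr_ref),
         IE_MR = clamp1(ctrl$ie[["mr"]] / g$ie_mr_ref),
         E_BP = clamp1(e_bp / g$e_bp_ref),
         IE_BP = clamp1(ctrl$ie[["bp"]] / g$ie_bp_ref))
  M <- lapply(x, function(v) part_memberships(ctrl$in_part, v))
  labs_idx <- vapply(x, function(v)
    match(label_inputs(v, ctrl$in_part), input_labels()), integer(1))
  pairs <- decompose_inputs()
  ctrl$step <- ctrl$step + 1L
  incr <- c(atracurium = 0, isoflurane = 0)
  n_fired <- 0L
  added_before <- ctrl$n_added
  for (ch in ctrl$channels) {
    vals <- numeric(0); wts <- numeric(0)
    rec <- list(cells = vector("list", 6L),
                labels = cbind(labs_idx[pairs$var1], labs_idx[pairs$var2]))
    for (p in 1:6) {
      res <- pair_inference(ctrl, ctrl$rb[[ch]][[p]],
                            M[[pairs$var1[p]]], M[[pairs$var2[p]]])
      ctrl$totals[[ch]][p] <- ctrl$totals[[ch]][p] + 1L
      if (!is.null(res$fired)) {
        for (r in seq_len(nrow(res$fired)))
          ctrl$fires[[ch]][[p]][res$fired[r, 1L], res$fired[r, 2L]] <-
            ctrl$fires[[ch]][[p]][res$fired[r, 1L], res$fired[r, 2L]] + 1L
        n_fired <- n_fired + nrow(res$fired)
      }
      rec$cells[p] <- list(if (ctrl$blame == "all") res$fired
                           else res$fmax_cell)
      if (!is.na(res$crisp)) {
        vals <- c(vals, res$crisp)
        wts <- c(wts, res$fmax)
      }
    }
    if (length(vals)) {
      incr[ch] <- if (ctrl$combine == "weighted" && sum(wts) > 0)
        sum(wts * vals) / sum(wts) else mean(vals)
    }
    if (isTRUE(getOption("soflc.debug")))
      ctrl$detail[[length(ctrl$detail) + 1L]] <-
        list(step = ctrl$step, channel = ch, x = x, vals = vals,
             wts = wts, cells = rec$cells)
    # push history (ring of length max delay + 1)
    h <- ctrl$history[[ch]]
    hi <- (ctrl$step - 1L) %% length(h) + 1L
    h[[hi]] <- rec
    ctrl$history[[ch]] <- h
    if (ctrl$self_organize) {
      chan <- if (ch == "atracurium") c("E_MR", "IE_MR") else
        c("E_BP", "IE_BP")
      corr <- pi_lookup(ctrl$pim,
                        input_labels()[labs_idx[chan[1]]],
                        input_labels()[labs_idx[chan[2]]])
      resp <- ctrl$step - ctrl$delay[[ch]]
      if (resp >= 1L) {
        hrec <- ctrl$history[[ch]][[(resp - 1L) %% length(h) + 1L]]
        apply_correction(ctrl, ch, corr, hrec)
      }
    }
  }
  list(du1 = g$track_mr * (g$out_mr * incr[["atracurium"]] - u1) * dt,
       du2 = g$track_bp * (g$out_bp * incr[["isoflurane"]] - u2) * dt,
       n_fired = n_fired,
       n_added = ctrl$n_added - added_before)
}

# shift the maximally-firing rule of each subsystem at the responsible
# step by the correction offset; create a rule where none fired
apply_correction <- function(ctrl, ch, corr, hrec) {
  off <- correction_offset(corr)
  nout <- length(output_labels())
  for (p in 1:6) {
    cell <- hrec$cells[[p]]
    if (is.null(cell)) {
      # forced generation at the responsible step's antecedent signature
      i <- hrec$labels[p, 1L]; j <- hrec$labels[p, 2L]
      if (ctrl$rb[[ch]][[p]][i, j] == 0L) {
        newc <- min(nout, max(1L, 1L + off))
        ctrl$rb[[ch]][[p]][i, j] <- newc
        ctrl$n_added <- ctrl$n_added + 1L
        ctrl$change_log[[length(ctrl$change_log) + 1L]] <-
          list(step = ctrl$step, channel = ch, pair = p, cell = c(i, j),
               old = 0L, new = newc)
      }
    } else if (off != 0L) {
      cells <- if (is.matrix(cell)) cell else matrix(cell, ncol = 2L)
      for (r in seq_len(nrow(cells))) {
        i <- cells[r, 1L]; j <- cells[r, 2L]
        old <- ctrl$rb[[ch]][[p]][i, j]
        if (old == 0L) next
        newc <- min(nout, max(1L, old + off))
        if (newc != old) {
          ctrl$rb[[ch]][[p]][i, j] <- newc
          ctrl$change_log[[length(ctrl$change_log) + 1L]] <-
            list(step = ctrl$step, channel = ch, pair = p, cell = c(i, j),
                 old = old, new = newc)
        }
      }
    }
  }
  invisible(ctrl)
}

#' Apply one self-organizing correction to a rule-base
#'
#' The functional core of the rule-modification layer, exposed for direct
#' use: given a correction label, the maximally-firing rule signature per
#' decomposed subsystem, and the crisp input labels at the responsible
#' step, shifts each fired rule's consequent by the correction's signed
#' offset (saturating within ZE..PB) and creates a rule with consequent
#' `saturate(ZE + offset)` for subsystems where no rule fired. A ZE
#' correction with all subsystems fired leaves the rule-base unchanged;
#' identical resulting rules are never duplicated (rules are keyed by
#' antecedent signature).
#'
#' @param rb a [rulebase()].
#' @param correction correction label from [pi_lookup()].
#' @param fired data frame (or list) with columns `pair`, `in1_label`,
#'   `in2_label`: the maximally-firing rule per subsystem; missing pairs
#'   are treated as "no rule fired".
#' @param input_labels_now named character vector of crisp labels for
#'   `E_MR`, `IE_MR`, `E_BP`, `IE_BP` (used for forced generation).
#' @return list with the modified `rulebase` and a `changes` data frame.
#' @export
so_update <- function(rb, correction, fired = NULL,
                      input_labels_now = NULL) {
  stopifnot(inherits(rb, "rulebase"))
  mats <- rb_to_matrices(rb)
  off <- correction_offset(correction)
  labs <- input_labels()
  nout <- length(output_labels())
  fired <- if (is.null(fired)) data.frame(pair = integer(0))
           else as.data.frame(fired)
  changes <- list()
  pairs <- decompose_inputs()
  for (p in 1:6) {
    row <- which(fired$pair == p)
    if (length(row)) {
      i <- match(fired$in1_label[row[1]], labs)
      j <- match(fired$in2_label[row[1]], labs)
      old <- mats[[p]][i, j]
      if (old == 0L || off == 0L) next
      newc <- min(nout, max(1L, old + off))
      if (newc != old) {
        mats[[p]][i, j] <- newc
        changes[[length(changes) + 1L]] <-
          data.frame(pair = p, in1_label = labs[i], in2_label = labs[j],
                     old = output_labels()[old],
                     new = output_labels()[newc])
      }
    } else if (!is.null(input_labels_now)) {
      i <- match(input_labels_now[[pairs$var1[p]]], labs)
      j <- match(input_labels_now[[pairs$var2[p]]], labs)
      if (is.na(i) || is.na(j)) next
      if (mats[[p]][i, j] == 0L) {
        newc <- min(nout, max(1L, 1L + off))
        mats[[p]][i, j] <- newc
        changes[[length(changes) + 1L]] <-
          data.frame(pair = p, in1_label = labs[i], in2_label = labs[j],
                     old = NA_character_, new = output_labels()[newc])
      }
    }
  }
  list(rulebase = matrices_to_rb(mats, rb$output),
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame())
}

#' Firing percentages of a controller's rules
#'
#' The firing percentage of a rule is 100 times the number of inference
#' operations in which it fired divided by the total number of inference
#' operations of its decomposed subsystem.
#'
#' @param ctrl a [soflc_controller()] after a run (or a list with
#'   `fires`/`totals` in the same layout).
#' @param channel `"atracurium"` or `"isoflurane"`.
#' @return data frame with columns `pair`, `in1_var`, `in1_label`,
#'   `in2_var`, `in2_label`, `consequent_label`, `fires`, `total`,
#'   `percent`, one row per rule currently in the rule-base.
#' @export
firing_percentages <- function(ctrl, channel = c("atracurium", "isoflurane")) {
  channel <- match.arg(channel)
  labs <- input_labels()
  pairs <- decompose_inputs()
  rows <- list()
  for (p in 1:6) {
    total <- ctrl$totals[[channel]][p]
    if (total == 0L)
      stop("no inference operations recorded for pair ", p, call. = FALSE)
    idx <- which(ctrl$rb[[channel]][[p]] > 0L, arr.ind = TRUE)
    if (!nrow(idx)) next
    fires <- ctrl$fires[[channel]][[p]][idx]
    rows[[p]] <- data.frame(
      pair = p,
      in1_var = pairs$var1[p], in1_label = labs[idx[, 1]],
      in2_var = pairs$var2[p], in2_label = labs[idx[, 2]],
      consequent_label = output_labels()[ctrl$rb[[channel]][[p]][idx]],
      fires = fires, total = total, percent = 100 * fires / total,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the non-trivial rules of a rule-base
#'
#' Removes rules fired in less than `threshold` percent of inference
#' operations (trivial rules, typically fired only by noise), returning
#' the reduced rule-base that can seed subsequent runs.
#'
#' @param rb a [rulebase()] (usually the post-run rule-base, see
#'   [controller_rulebase()]).
#' @param stats firing statistics from [firing_percentages()] for the
#'   same channel.
#' @param threshold percentage below which a rule is trivial (default 1).
#' @return the reduced [rulebase()].
#' @export
extract_rules <- function(rb, stats, threshold = 1) {
  stopifnot(inherits(rb, "rulebase"), threshold >= 0)
  key <- function(df) paste(df$in1_var, df$in1_label, df$in2_var,
                            df$in2_label)
  pct <- stats$percent[match(key(rb$rules), key(stats))]
  pct[is.na(pct)] <- 0
  keep <- pct >= threshold
  if (!any(keep))
    warning("extraction removed every rule: the controller would be inert",
            call. = FALSE)
  rulebase(rb$rules[keep, , drop = FALSE], output = rb$output)
}

#' Current rule-base of a controller channel
#'
#' @param ctrl a [soflc_controller()].
#' @param channel `"atracurium"` or `"isoflurane"`.
#' @return a [rulebase()] reflecting any self-organized changes.
#' @export
controller_rulebase <- function(ctrl,
                                channel = c("atracurium", "isoflurane")) {
  channel <- match.arg(channel)
  matrices_to_rb(ctrl$rb[[channel]], channel)
}

#' @export
print.soflc_controller <- function(x, ...) {
  cat(sprintf("<soflc_controller> %s, %d + %d rules, step %d\n", x$kind,
              sum(vapply(x$rb$atracurium, function(m) sum(m > 0), 0)),
              sum(vapply(x$rb$isoflurane, function(m) sum(m > 0), 0)),
              x$step))
  invisible(x)
}
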