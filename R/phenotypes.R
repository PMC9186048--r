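#' Default extracellular-flux injection protocol
#'
#' The 18-measurement worm protocol: measurements 1-5 at baseline, 6-14
#' after FCCP injection (maximal, uncoupled respiration), 15-18 after sodium
#' azide (non-mitochondrial respiration). Measurement 1 is excluded from the
#' basal average, which uses measurements 2 through 5.
#'
#' @return list with index vectors `basal`, `fccp`, `azide` and
#'   `n_measurements`
#' @export
ocr_protocol <- function() {
  list(basal = 2:5, fccp = 6:14, azide = 15:18, n_measurements = 18L)
}

#' Derive respiration states from an OCR trace
#'
#' Non-mitochondrial respiration is the mean OCR after azide injection;
#' basal respiration is the mean of measurements 2-5 minus non-mitochondrial;
#' maximal respiration is the mean post-FCCP OCR minus non-mitochondrial;
#' spare capacity is maximal minus basal. All four states are then divided
#' by the number of worms in the well. Negative derived values (e.g. an
#' FCCP plateau below baseline) are reported with a flag, never clipped.
#'
#' @param measurements numeric vector of per-well OCR values
#'   (pmol O2/min); length must match the protocol
#' @param n_worms worms in the well (>= 1)
#' @param protocol index protocol, defaults to [ocr_protocol()]
#' @return one-row data.frame: `basal`, `maximal`, `spare`, `nonmito`
#'   (pmol O2/min per worm) and `flag_negative`
#' @examples
#' ocr_derive(c(rep(100, 5), rep(150, 9), rep(20, 4)), n_worms = 1)
#' @export
ocr_derive <- function(measurements, n_worms = 1, protocol = ocr_protocol()) {
  if (length(measurements) != protocol$n_measurements)
    stop("expected ", protocol$n_measurements, " measurements, got ",
         length(measurements), " (pass a custom protocol for other designs)")
  stopifnot(n_worms >= 1)
  nonmito <- mean(measurements[protocol$azide])
  basal <- mean(measurements[protocol$basal]) - nonmito
  maximal <- mean(measurements[protocol$fccp]) - nonmito
  spare <- maximal - basal
  out <- data.frame(basal = basal, maximal = maximal, spare = spare,
                    nonmito = nonmito) / n_worms
  out$flag_negative <- any(out[1, c("basal", "maximal", "spare")] < 0)
  out
}

#' Derive respiration states for a plate of traces
#'
#' @param traces data.frame with `well_id`, `n_worms`, grouping columns, and
#'   measurement columns `m01`..`m18` (as written by
#'   [generate_ocr_traces()])
#' @param protocol index protocol, defaults to [ocr_protocol()]
#' @return data.frame of per-well [ocr_derive()] summaries joined to the
#'   grouping columns
#' @export
ocr_derive_all <- function(traces, protocol = ocr_protocol()) {
  mcols <- sprintf("m%02d", seq_len(protocol$n_measurements))
  stopifnot(all(mcols %in% names(traces)))
  derived <- do.call(rbind, lapply(seq_len(nrow(traces)), function(i)
    ocr_derive(as.numeric(traces[i, mcols]), traces$n_worms[i], protocol)))
  cbind(traces[setdiff(names(traces), mcols)], derived)
}

#' Group-level respiration summary and factorial test
#'
#' Summarises per-worm respiration states by design cell and tests each of
#' the four states with a two-way ANOVA with interaction (the same engine as
#' the metabolite screen).
#'
#' @param summaries output of [ocr_derive_all()]
#' @param factorA,factorB design columns (default strain and treatment)
#' @param alpha omnibus threshold forwarded to [anova_twoway()]
#' @return list: `means` (per-cell mean/SD/n per state), `anova` (per-state
#'   p-values), `posthoc` (Tukey contrasts for states crossing `alpha`)
#' @export
group_respiration <- function(summaries, factorA = "strain",
                              factorB = "treatment", alpha = 0.05) {
  states <- c("basal", "maximal", "spare", "nonmito")
  stopifnot(all(states %in% names(summaries)))
  cellm <- stats::aggregate(summaries[states],
                            by = list(A = summaries[[factorA]],
                                      B = summaries[[factorB]]),
                            function(x) c(mean = mean(x), sd = stats::sd(x),
                                          n = length(x)))
  names(cellm)[1:2] <- c(factorA, factorB)
  m <- t(as.matrix(summaries[states]))
  colnames(m) <- summaries$well_id
  meta <- data.frame(sample_id = summaries$well_id,
                     A = summaries[[factorA]], B = summaries[[factorB]])
  fit <- anova_twoway(m, meta, "A", "B", alpha = alpha)
  names(fit$results)[names(fit$results) == "feature_id"] <- "state"
  list(means = cellm, anova = fit$results, posthoc = fit$posthoc)
}

#' Kaplan-Meier survival summary per group
#'
#' Product-limit survival curves with per-group median and mean lifespan.
#' The mean is the area under the survival curve up to the largest observed
#' time in the group (the restricted mean); it is flagged when that largest
#' time is censored, in which case the plain mean is undefined.
#'
#' @param records data.frame with `time` (> 0), `event` (1 = dead,
#'   0 = censored) and a grouping column
#' @param group name of the grouping column
#' @return object of class `km_fit`: `curves` (data.frame `group`, `time`,
#'   `n_risk`, `n_event`, `surv`) and `summary` (per-group `n`, `events`,
#'   `median`, `mean`, `mean_restricted` flag)
#' @export
km_estimate <- function(records, group = "group") {
  stopifnot(all(records$time > 0), all(records$event %in% c(0, 1)))
  g <- factor(records[[group]])
  if (any(tapply(records$event, g, sum) == 0))
    warning("group(s) with no events: restricted means only")
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data =
                             cbind(records, g = g))
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time),
                                                     levels(g)[1])
            else fit$strata
  grp <- rep(sub("^g=", "", names(strata)), strata)
  curves <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv)
  summ <- do.call(rbind, lapply(levels(g), function(lv) {
    d <- records[g == lv, , drop = FALSE]
    cv <- curves[curves$group == lv, , drop = FALSE]
    tmax <- max(d$time)
    # area under the step function from 0 to the largest observed time
    tt <- c(0, cv$time[cv$n_event > 0])
    ss <- c(1, cv$surv[cv$n_event > 0])
    tt <- tt[tt <= tmax]
    ss <- ss[seq_along(tt)]
    auc <- sum(ss * diff(c(tt, tmax)))
    med <- cv$time[cv$surv <= 0.5][1]
    data.frame(group = lv, n = nrow(d), events = sum(d$event),
               median = med, mean = auc,
               mean_restricted = d$event[which.max(d$time)] == 0)
  }))
  structure(list(curves = curves, summary = summ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Log-rank test between two groups
#'
#' @param records data.frame with `time`, `event`, and a grouping column
#'   with exactly two non-empty levels
#' @param group grouping column name
#' @return list: `chisq` (1-df log-rank statistic), `p_value`
#' @export
logrank_test <- function(records, group = "group") {
  g <- factor(records[[group]])
  if (nlevels(g) != 2L || any(table(g) == 0))
    stop("log-rank test needs exactly two non-empty groups")
  if (sum(records$event) == 0) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(records, g = g))
  list(chisq = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
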