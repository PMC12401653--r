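#' Adjudicate one proficiency-test result
#'
#' Applies the censoring-aware verdict semantics of interlaboratory-test
#' reporting:
#' * a numeric calculated concentration passes iff it lies inside the
#'   accepted range (bounds inclusive);
#' * a censored result "< L" (detected but below the quantification limit)
#'   is `Passed_below_LLOQ` when the accepted range reaches below `L`
#'   (`accepted_low < L`), i.e. a sub-LLOQ detection is consistent with the
#'   organizer's range - and `Failed` otherwise, since a quantifiable
#'   result was expected;
#' * `nd` (no peak detected) is always a failure, annotated
#'   `Failed_below_LLOQ` when the target itself lies below the LLOQ.
#'
#' @param entry one PT row (list or one-row `data.frame`) with `status`
#'   (`value`, `censored_lt`, `nd`), `calculated`, `censor_limit`,
#'   `target`, `accepted_low`, `accepted_high`.
#' @param lloq LLOQ used for censoring semantics; defaults to the entry's
#'   own `lloq` (or its censoring limit).
#' @return list of class `ptVerdict`: `verdict` (one of `Passed`, `Failed`,
#'   `Passed_below_LLOQ`, `Failed_below_LLOQ`) and `rationale`.
#' @examples
#' adjudicate(list(status = "value", calculated = 67, target = 53,
#'                 accepted_low = 26.6, accepted_high = 79.4), lloq = 50)
#' @export
adjudicate <- function(entry, lloq = NULL) {
  e <- as.list(entry)
  if (is.null(lloq) || is.na(lloq)) {
    lloq <- if (!is.null(e$lloq) && is.finite(as.numeric(e$lloq))) {
      as.numeric(e$lloq)
    } else if (identical(e$status, "censored_lt")) {
      e$censor_limit
    } else {
      NA_real_
    }
  }
  out <- switch(e$status,
    value = {
      inRange <- e$calculated >= e$accepted_low &
        e$calculated <= e$accepted_high
      list(
        verdict = if (inRange) "Passed" else "Failed",
        rationale = sprintf("calculated %g %s accepted range [%g, %g]",
                            e$calculated,
                            if (inRange) "inside" else "outside",
                            e$accepted_low, e$accepted_high))
    },
    censored_lt = {
      lim <- if (is.finite(e$censor_limit)) e$censor_limit else lloq
      if (!is.finite(lim)) stop("lloq missing for censored result")
      if (e$accepted_low < lim) {
        list(verdict = "Passed_below_LLOQ",
             rationale = sprintf(
               "detected below LLOQ %g; accepted range [%g, %g] reaches below it",
               lim, e$accepted_low, e$accepted_high))
      } else {
        list(verdict = "Failed",
             rationale = sprintf(
               "reported < %g but the accepted range [%g, %g] lies entirely above",
               lim, e$accepted_low, e$accepted_high))
      }
    },
    nd = {
      if (!is.finite(lloq)) stop("lloq missing for analyte")
      if (e$target < lloq) {
        list(verdict = "Failed_below_LLOQ",
             rationale = sprintf(
               "not detected; target %g below LLOQ %g", e$target, lloq))
      } else {
        list(verdict = "Failed",
             rationale = sprintf(
               "not detected although target %g is quantifiable (LLOQ %g)",
               e$target, lloq))
      }
    },
    stop("unknown PT status: ", e$status)
  )
  class(out) <- "ptVerdict"
  out
}

#' @export
print.ptVerdict <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$verdict, x$rationale))
  invisible(x)
}

.verdictCore <- function(v) ifelse(grepl("^Passed", v), "Passed", "Failed")

#' Adjudicate a proficiency-test table
#'
#' Per-row verdicts for a parsed PT table (see [readPTTable()]), with an
#' optional concordance summary against a reference comment column.
#' Concordance compares the Passed/Failed core of the verdicts; the
#' "(< LLOQ)" annotation is reported but not compared, since its printed
#' usage is not fully consistent.
#'
#' @param pt PT `data.frame` from [readPTTable()].
#' @param panel optional [AnalytePanel-class] used to resolve LLOQs for
#'   rows that carry none of their own (unknown analytes error).
#' @param referenceComments optional character vector of reference
#'   comments; defaults to `pt$comment` when present.
#' @return list of class `ptAdjudication`: `verdicts` (the input plus
#'   `verdict`, `rationale` and, with references, `concordant`), and with
#'   references a `concordance` list (`n`, `n_concordant`,
#'   `concordance_pct`, `discordant` rows).
#' @examples
#' pt <- readPTTable(system.file("extdata", "pt_results.csv",
#'                               package = "etquant"))
#' adjudicateBatch(pt)$concordance$concordance_pct
#' @export
adjudicateBatch <- function(pt, panel = NULL, referenceComments = NULL) {
  if (is.null(referenceComments) && "comment" %in% names(pt)) {
    referenceComments <- pt$comment
  }
  if (nrow(pt) == 0L) {
    out <- list(verdicts = cbind(pt, verdict = character(),
                                 rationale = character()),
                concordance = NULL)
    class(out) <- "ptAdjudication"
    return(out)
  }
  verdicts <- character(nrow(pt))
  rationale <- character(nrow(pt))
  for (i in seq_len(nrow(pt))) {
    e <- as.list(pt[i, ])
    lloq <- if (!is.null(e$lloq) && is.finite(suppressWarnings(
      as.numeric(e$lloq)))) {
      as.numeric(e$lloq)
    } else if (!is.null(panel)) {
      if (!(e$analyte %in% names(panel))) stop("unknown analyte: ", e$analyte)
      panelEntry(panel, e$analyte)$lloq
    } else {
      NA_real_
    }
    v <- adjudicate(e, lloq = lloq)
    verdicts[i] <- v$verdict
    rationale[i] <- v$rationale
  }
  res <- pt
  res$verdict <- verdicts
  res$rationale <- rationale
  concordance <- NULL
  if (!is.null(referenceComments)) {
    refCore <- .verdictCore(trimws(referenceComments))
    res$concordant <- .verdictCore(verdicts) == refCore
    disc <- res[!res$concordant, , drop = FALSE]
    concordance <- list(
      n = nrow(res),
      n_concordant = sum(res$concordant),
      concordance_pct = 100 * mean(res$concordant),
      discordant = disc
    )
  }
  out <- list(verdicts = res, concordance = concordance)
  class(out) <- "ptAdjudication"
  out
}

#' @export
print.ptAdjudication <- function(x, ...) {
  cat(sprintf("PT adjudication: %d result(s)\n", nrow(x$verdicts)))
  print(table(x$verdicts$verdict))
  if (!is.null(x$concordance)) {
    cat(sprintf("Concordance with reference comments: %d/%d (%.1f%%)\n",
                x$concordance$n_concordant, x$concordance$n,
                x$concordance$concordance_pct))
    if (nrow(x$concordance$discordant)) {
      cat("Discordant rows:\n")
      d <- x$concordance$discordant
      for (i in seq_len(nrow(d))) {
        cat(sprintf("  %s: verdict %s vs reference '%s' (%s)\n",
                    d$analyte[i], d$verdict[i], d$comment[i],
                    d$rationale[i]))
      }
    }
  }
  invisible(x)
}
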