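# Dual-model remedying: route doubtful (or, with labels, incorrect)
# diagnoses from a main naive Bayes model to an alternative one and
# classify the outcome.

#' Doubt band membership
#'
#' A diagnosis is doubtful when its posterior probability of "positive" is
#' larger than `lower` and less than `upper` (an open interval by default:
#' a posterior of exactly 0.45 or 0.55 is not doubtful).
#'
#' @param p Posterior probability (vectorised).
#' @param lower,upper Band limits (defaults 0.45 and 0.55).
#' @param closed If `TRUE`, use the closed interval `[lower, upper]`.
#' @return Logical vector.
#' @export
in_doubt_band <- function(p, lower = 0.45, upper = 0.55, closed = FALSE) {
  stopifnot(all(p >= 0 & p <= 1))
  if (closed) p >= lower & p <= upper else p > lower & p < upper
}

#' Classify a remedy outcome from posterior probabilities
#'
#' Given the main model's and the remedying model's posterior probabilities
#' of "positive" for one instance, and (optionally) its true status,
#' labels the outcome:
#' \describe{
#'   \item{accepted}{the main posterior lies outside the doubt band (band
#'     mode only): the main diagnosis stands.}
#'   \item{corrected}{the main prediction was wrong and the remedying
#'     model's is right.}
#'   \item{improved}{the main prediction was right and the remedying model
#'     assigns a strictly higher probability to the correct class.}
#'   \item{unresolved}{neither of the above (e.g. both models land on the
#'     same wrong side, or the remedying model does not strictly improve a
#'     correct diagnosis).}
#' }
#' Without a true status only accepted/remedied routing is possible and the
#' conclusion is `NA`.
#'
#' @param main_posterior,remedy_posterior Posterior P(case) from the two
#'   models (vectorised).
#' @param true_status Optional true labels ("case"/"control").
#' @param check_band If `TRUE` (band mode), instances outside the doubt
#'   band are `accepted` without consulting the remedying model; if `FALSE`
#'   (audit of known errors), the conclusion rule is applied regardless.
#' @param lower,upper,closed Doubt band, see [in_doubt_band()].
#' @return Character vector of conclusions.
#' @export
remedy_conclusion <- function(main_posterior, remedy_posterior,
                              true_status = NULL, check_band = TRUE,
                              lower = 0.45, upper = 0.55, closed = FALSE) {
  n <- length(main_posterior)
  stopifnot(length(remedy_posterior) == n)
  band <- in_doubt_band(main_posterior, lower, upper, closed)
  out <- rep(NA_character_, n)
  if (check_band) out[!band] <- "accepted"
  todo <- if (check_band) band else rep(TRUE, n)
  if (is.null(true_status)) return(out)
  truth <- as_status(true_status)
  main_pred <- main_posterior >= 0.5
  alt_pred <- remedy_posterior >= 0.5
  is_case <- truth == "case"
  main_ok <- main_pred == is_case
  alt_ok <- alt_pred == is_case
  p_main_true <- ifelse(is_case, main_posterior, 1 - main_posterior)
  p_alt_true <- ifelse(is_case, remedy_posterior, 1 - remedy_posterior)
  out[todo & !main_ok & alt_ok] <- "corrected"
  out[todo & main_ok & (p_alt_true > p_main_true)] <- "improved"
  out[todo & is.na(out)] <- "unresolved"
  out
}

#' Remedy a single diagnosis with an alternative model
#'
#' Computes both models' posteriors for one instance; inside the doubt band
#' the final posterior is the remedying model's, outside it the main
#' model's stands (`accepted`). When the true status is supplied the
#' outcome is labelled per [remedy_conclusion()].
#'
#' @param main,alt Fitted [nbc_fit()] models (both must cover the
#'   instance's features).
#' @param instance Named 0/1 vector or one-row matrix of binary features.
#' @param true_status Optional true label.
#' @param lower,upper,closed Doubt band.
#' @return A list of class `remedy_outcome`: `main_posterior`,
#'   `remedy_posterior`, `final_posterior`, `predicted`, `conclusion`.
#' @export
remedy_instance <- function(main, alt, instance, true_status = NULL,
                            lower = 0.45, upper = 0.55, closed = FALSE) {
  pm <- posterior_positive(main, instance)
  pa <- posterior_positive(alt, instance)
  band <- in_doubt_band(pm, lower, upper, closed)
  final <- ifelse(band, pa, pm)
  concl <- remedy_conclusion(pm, pa, true_status, check_band = TRUE,
                             lower = lower, upper = upper, closed = closed)
  structure(list(main_posterior = pm, remedy_posterior = pa,
                 final_posterior = final,
                 predicted = ifelse(final >= 0.5, "case", "control"),
                 conclusion = concl),
            class = "remedy_outcome")
}

#' @export
print.remedy_outcome <- function(x, ...) {
  cat(sprintf("Remedy outcome: main %.4f, remedy %.4f -> final %.4f (%s)%s\n",
              x$main_posterior, x$remedy_posterior, x$final_posterior,
              x$predicted,
              if (!is.na(x$conclusion)) paste0(", ", x$conclusion) else ""))
  invisible(x)
}

#' Remedy table for a whole dataset
#'
#' Applies the dual-model remedy to every instance. In `"band"` mode
#' (production: labels may be absent) only instances whose main posterior
#' falls in the doubt band are routed to the alternative model. In
#' `"audit"` mode (labels required) the examined set additionally includes
#' every main-model error, whatever its posterior -- the setting in which
#' published remedy tables list errors with posteriors outside the band.
#'
#' @param main,alt Fitted [nbc_fit()] models.
#' @param x `binary_matrix` or 0/1 matrix covering both models' features.
#' @param status True labels (required for `mode = "audit"`; optional for
#'   `"band"`).
#' @param mode `"band"` or `"audit"`.
#' @param lower,upper,closed Doubt band.
#' @return A list of class `remedy_table`: `outcomes` (data.frame over the
#'   examined instances), `summary` (counts of
#'   accepted/corrected/improved/unresolved), `final_posterior` and
#'   `predicted` for all instances, and `accuracy` (main, alt, combined)
#'   when labels are available.
#' @export
remedy_table <- function(main, alt, x, status = NULL,
                         mode = c("band", "audit"),
                         lower = 0.45, upper = 0.55, closed = FALSE) {
  mode <- match.arg(mode)
  if (inherits(x, "binary_matrix")) {
    if (is.null(status)) status <- x$status
    V <- x$values
  } else V <- as.matrix(x)
  truth <- if (!is.null(status)) as_status(status)
  if (mode == "audit" && is.null(truth))
    stop("audit mode needs true labels", call. = FALSE)
  pm <- posterior_positive(main, V)
  pa <- posterior_positive(alt, V)
  band <- in_doubt_band(pm, lower, upper, closed)
  examined <- band
  if (mode == "audit") {
    main_wrong <- (pm >= 0.5) != (truth == "case")
    examined <- band | main_wrong
  }
  final <- ifelse(examined, pa, pm)
  predicted <- factor(ifelse(final >= 0.5, "case", "control"),
                      levels = c("control", "case"))
  concl <- rep(NA_character_, length(pm))
  if (!is.null(truth)) {
    concl[examined] <- remedy_conclusion(pm[examined], pa[examined],
                                         truth[examined], check_band = FALSE,
                                         lower = lower, upper = upper,
                                         closed = closed)
    concl[!examined] <- "accepted"
  } else concl[!examined] <- "accepted"
  outcomes <- data.frame(
    instance = which(examined),
    true_status = if (!is.null(truth)) as.character(truth[examined]) else NA,
    main_posterior = pm[examined],
    remedy_posterior = pa[examined],
    final_posterior = final[examined],
    conclusion = concl[examined],
    row.names = NULL)
  summary <- table(factor(concl, levels = c("accepted", "corrected",
                                            "improved", "unresolved")))
  acc <- NULL
  if (!is.null(truth)) {
    acc <- c(main = mean((pm >= 0.5) == (truth == "case")),
             alt = mean((pa >= 0.5) == (truth == "case")),
             combined = mean((final >= 0.5) == (truth == "case")))
  }
  structure(list(outcomes = outcomes, summary = summary,
                 final_posterior = final, predicted = predicted,
                 accuracy = acc, mode = mode),
            class = "remedy_table")
}

#' Worked examples of the remedying procedure
#'
#' A curated table of remedy worked examples bundled with the package: each
#' row gives a main-model posterior of "positive", the remedying model's
#' posterior, the instance's true status, and the expected outcome label.
#' The `doubt_band` rows exercise the in-band routing (all main posteriors
#' inside the open band (0.45, 0.55)); the `errors` rows are incorrect main
#' diagnoses audited regardless of band, all of which the second expert
#' corrects. Used to validate [remedy_conclusion()].
#'
#' @return A data.frame with columns `table`, `panel`, `instance`,
#'   `true_status`, `main_posterior`, `remedy_posterior`, `conclusion`.
#' @export
remedy_worked_examples <- function() {
  path <- system.file("extdata", "remedy_worked_examples.tsv",
                      package = "snpdx", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @export
print.remedy_table <- function(x, ...) {
  cat("Remedy table (", x$mode, " mode): ", nrow(x$outcomes),
      " instance(s) examined\n", sep = "")
  print(x$summary)
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy: main %.4f, alt %.4f, combined %.4f\n",
                x$accuracy[["main"]], x$accuracy[["alt"]],
                x$accuracy[["combined"]]))
  invisible(x)
}
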