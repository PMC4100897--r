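#' Construct a lottery
#'
#' A lottery is a finite set of strictly positive money prizes with associated
#' outcome probabilities. Probabilities must sum to one.
#'
#' @param prizes numeric vector of strictly positive money amounts.
#' @param probs numeric vector of outcome probabilities, same length as
#'   \code{prizes}, each in \eqn{[0, 1]}, summing to 1.
#' @return An object of class \code{"lottery"}.
#' @examples
#' lottery(c(2, 1.6), c(0.1, 0.9))
#' @export
lottery <- function(prizes, probs) {
  if (!is.numeric(prizes) || !is.numeric(probs))
    stop("`prizes` and `probs` must be numeric")
  if (length(prizes) != length(probs) || length(prizes) < 1L)
    stop("`prizes` and `probs` must have equal length >= 1")
  if (any(!is.finite(prizes)) || any(!is.finite(probs)))
    stop("`prizes` and `probs` must be finite")
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 (within 1e-12)")
  if (any(prizes <= 0))
    stop("prizes must be strictly positive")
  structure(list(prizes = as.numeric(prizes), probs = as.numeric(probs)),
            class = "lottery")
}

#' @export
print.lottery <- function(x, ...) {
  cat("Lottery:",
      paste(sprintf("(%.4g: %.4g)", x$probs, x$prizes), collapse = " "),
      "\n")
  invisible(x)
}

#' Expected value of a lottery
#'
#' @param x a \code{\link{lottery}}.
#' @return The probability-weighted mean prize.
#' @examples
#' expected_value(lottery(c(2, 1.6), c(0.1, 0.9))) # 1.64
#' @export
expected_value <- function(x) {
  stopifnot(inherits(x, "lottery"))
  sum(x$probs * x$prizes)
}

#' Construct a lottery pair (one multiple price list row)
#'
#' Both options of a price-list row share the same probability vector; only
#' the prizes differ.
#'
#' @param option_a,option_b \code{\link{lottery}} objects with identical
#'   probability vectors.
#' @param row integer row index within the price list (1-based).
#' @param scale positive payout multiplier of the list the pair belongs to.
#' @return An object of class \code{"lottery_pair"}.
#' @export
lottery_pair <- function(option_a, option_b, row = 1L, scale = 1) {
  stopifnot(inherits(option_a, "lottery"), inherits(option_b, "lottery"))
  if (length(option_a$probs) != length(option_b$probs) ||
      any(abs(option_a$probs - option_b$probs) > 1e-12))
    stop("both options of a price-list row must share the same probability vector")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("`scale` must be a positive number")
  structure(list(option_a = option_a, option_b = option_b,
                 row = as.integer(row), scale = as.numeric(scale)),
            class = "lottery_pair")
}

# prizes of the baseline Holt-Laury price list: safe option (2.00 vs 1.60)
# against risky option (3.85 vs 0.10)
HL_PRIZES <- c(a_high = 2.00, a_low = 1.60, b_high = 3.85, b_low = 0.10)

#' The Holt-Laury multiple price list
#'
#' Builds the canonical 10-row Holt-Laury design: row \eqn{k} offers the
#' "safe" lottery A \eqn{(k/10, 2.00; 1-k/10, 1.60)} against the "risky"
#' lottery B \eqn{(k/10, 3.85; 1-k/10, 0.10)}, with all prizes multiplied by
#' \code{scale}. Row 10 is degenerate (the high prize is certain) and acts as
#' a comprehension check: option B dominates for every risk attitude.
#'
#' @param scale positive payout multiplier (1 for the baseline list, 5 for
#'   the scaled-up list).
#' @return An object of class \code{"mpl_design"}: a list with elements
#'   \code{pairs} (ten \code{\link{lottery_pair}}s) and \code{scale}.
#' @examples
#' d <- hl_design()
#' expected_value(d$pairs[[1]]$option_a) # 1.64
#' @export
hl_design <- function(scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a positive number")
  pairs <- lapply(1:10, function(k) {
    p <- k / 10
    probs <- if (k == 10) c(1, 0) else c(p, 1 - p)
    lottery_pair(
      lottery(scale * HL_PRIZES[c("a_high", "a_low")], probs),
      lottery(scale * HL_PRIZES[c("b_high", "b_low")], probs),
      row = k, scale = scale
    )
  })
  structure(list(pairs = pairs, scale = scale), class = "mpl_design")
}

#' @export
print.mpl_design <- function(x, ...) {
  cat(sprintf("Multiple price list: %d rows, payout scale %g\n",
              length(x$pairs), x$scale))
  invisible(x)
}

#' Default design registry for the two-payout-scale experiment
#'
#' Maps task identifiers to price-list designs. The default reproduces the
#' two tasks of the experiment emulated by the package: the baseline list
#' (\code{"low"}, scale 1) and the list with all payouts multiplied by five
#' (\code{"high"}).
#'
#' @param scales named numeric vector of payout scales; names become task
#'   identifiers.
#' @return Named list of \code{\link{hl_design}} objects.
#' @export
hl_registry <- function(scales = c(low = 1, high = 5)) {
  if (is.null(names(scales)) || any(names(scales) == ""))
    stop("`scales` must be a named vector; names are task identifiers")
  lapply(scales, hl_design)
}

#' CRRA indifference point of a lottery pair
#'
#' Solves \eqn{EU_A(r) = EU_B(r)} for the relative risk aversion coefficient
#' \eqn{r} under the normalized CRRA utility
#' \eqn{u(x) = (x^{1-r}-1)/(1-r)} (with the \eqn{\ln x} limit at
#' \eqn{r = 1}). The normalization is an affine shift of the plain CRRA form
#' that leaves expected-utility differences' sign structure unchanged while
#' keeping the objective continuous through \eqn{r = 1}, so the bisection can
#' cross it. For a price list, the crossover of row \eqn{k} is the upper
#' endpoint of the implied RRA interval of a subject who switches from option
#' A to option B after row \eqn{k}.
#'
#' @param pair a \code{\link{lottery_pair}}.
#' @param lower,upper search interval for \eqn{r}.
#' @param tol root-finding tolerance.
#' @return The indifference \eqn{r}; \code{Inf} when option B dominates for
#'   every \eqn{r} in the interval (the degenerate last row), \code{-Inf}
#'   when option A dominates.
#' @examples
#' d <- hl_design()
#' crra_crossover(d$pairs[[9]]) # ~ 1.37
#' crra_crossover(d$pairs[[10]]) # Inf (B dominates)
#' @export
crra_crossover <- function(pair, lower = -5, upper = 5, tol = 1e-10) {
  stopifnot(inherits(pair, "lottery_pair"))
  f <- function(r) {
    sum(pair$option_a$probs * crra_utility(pair$option_a$prizes, r, normalized = TRUE)) -
      sum(pair$option_b$probs * crra_utility(pair$option_b$prizes, r, normalized = TRUE))
  }
  grid <- seq(lower, upper, length.out = 201L)
  fg <- vapply(grid, f, numeric(1))
  if (all(fg < 0)) return(Inf)   # B preferred at every r: no switch point
  if (all(fg > 0)) return(-Inf)  # A preferred at every r
  i <- which(fg[-length(fg)] * fg[-1] <= 0)[1L]
  if (is.na(i))
    stop("no sign change found in the search interval and neither option dominates")
  stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = tol)$root
}

#' Price-list summary table
#'
#' Renders a design as a data frame mirroring the printed layout of the
#' Holt-Laury table: probabilities, prizes, expected values, their
#' difference, and the implied open RRA interval \code{(rra_lower,
#' rra_upper)} for a subject who switches to option B at each row. Crossover
#' endpoints are rounded half-away-from-zero to \code{digits} decimals, the
#' convention of the printed table.
#'
#' @param design an \code{\link{mpl_design}} (default: baseline Holt-Laury).
#' @param digits decimals for the rounded RRA columns; use \code{NULL} for
#'   unrounded values.
#' @return A data frame with one row per price-list row.
#' @export
hl_table <- function(design = hl_design(), digits = 2) {
  stopifnot(inherits(design, "mpl_design"))
  rows <- lapply(design$pairs, function(pr) {
    data.frame(
      row = pr$row,
      p_high = pr$option_a$probs[1],
      a_high = pr$option_a$prizes[1], a_low = pr$option_a$prizes[2],
      b_high = pr$option_b$prizes[1], b_low = pr$option_b$prizes[2],
      ev_a = expected_value(pr$option_a),
      ev_b = expected_value(pr$option_b)
    )
  })
  out <- do.call(rbind, rows)
  out$ev_diff <- out$ev_a - out$ev_b
  cross <- vapply(design$pairs, crra_crossover, numeric(1))
  if (!is.null(digits)) cross <- round_half_away(cross, digits)
  out$rra_lower <- c(-Inf, cross[-length(cross)])
  out$rra_upper <- cross
  out
}

RESPONSE_LEVELS <- c("A", "B", "INDIFFERENT")

#' Assemble a validated choice dataset
#'
#' Bundles per-subject, per-task lottery-choice records with the design
#' registry that resolves each \code{(task_id, row_index)} to a lottery pair.
#' Records are validated: admissible response codes, resolvable tasks and
#' rows, no duplicated (subject, task, row) triples.
#'
#' @param records data frame with columns \code{subject_id}, \code{task_id},
#'   \code{row_index}, \code{response} (one of \code{"A"}, \code{"B"},
#'   \code{"INDIFFERENT"}).
#' @param designs named list of \code{\link{mpl_design}}s keyed by task id;
#'   defaults to the two-scale registry of \code{\link{hl_registry}}.
#' @return An object of class \code{"choice_data"}.
#' @export
choice_data <- function(records, designs = hl_registry()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("subject_id", "task_id", "row_index", "response")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records are missing required columns: ",
         paste(missing_cols, collapse = ", "))
  records <- records[need]
  records$subject_id <- as.character(records$subject_id)
  records$task_id <- as.character(records$task_id)
  records$row_index <- as.integer(records$row_index)
  records$response <- as.character(records$response)

  bad <- which(!records$response %in% RESPONSE_LEVELS)
  if (length(bad))
    stop(sprintf("invalid response code(s) %s at record(s) %s; admissible codes: %s",
                 paste(unique(records$response[bad]), collapse = ", "),
                 paste(utils::head(bad, 5L), collapse = ", "),
                 paste(RESPONSE_LEVELS, collapse = ", ")))
  unknown_task <- setdiff(unique(records$task_id), names(designs))
  if (length(unknown_task))
    stop("task id(s) not in the design registry: ",
         paste(unknown_task, collapse = ", "))
  for (tid in unique(records$task_id)) {
    nrows <- length(designs[[tid]]$pairs)
    bad_row <- records$task_id == tid &
      (is.na(records$row_index) | records$row_index < 1L | records$row_index > nrows)
    if (any(bad_row))
      stop(sprintf("row_index out of range 1..%d for task '%s' at record(s) %s",
                   nrows, tid,
                   paste(utils::head(which(bad_row), 5L), collapse = ", ")))
  }
  key <- paste(records$subject_id, records$task_id, records$row_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (subject_id, task_id, row_index) triple(s), e.g. record ",
         which(duplicated(key))[1L])

  structure(list(records = records, designs = designs), class = "choice_data")
}

#' @export
print.choice_data <- function(x, ...) {
  cs <- table(x$records$subject_id)
  cat(sprintf("Choice dataset: %d records, %d subjects (cluster sizes %d-%d), %d task(s)\n",
              nrow(x$records), length(cs), min(cs), max(cs),
              length(unique(x$records$task_id))))
  print(table(x$records$response))
  invisible(x)
}

#' @export
summary.choice_data <- function(object, ...) {
  cs <- table(object$records$subject_id)
  structure(list(
    n_records = nrow(object$records),
    n_subjects = length(cs),
    cluster_sizes = as.integer(cs),
    responses = table(object$records$response),
    tasks = unique(object$records$task_id)
  ), class = "summary.choice_data")
}

#' @export
print.summary.choice_data <- function(x, ...) {
  cat(sprintf("%d records from %d subjects (complete subject = %d records)\n",
              x$n_records, x$n_subjects, max(x$cluster_sizes)))
  print(x$responses)
  invisible(x)
}

#' @export
as.data.frame.choice_data <- function(x, ...) x$records

#' Read / write choice data as CSV
#'
#' The on-disk format is a comma-delimited UTF-8 file with header columns
#' \code{subject_id, task_id, row_index, response}. Reading validates the
#' records against the design registry; the round trip is lossless.
#'
#' @param path file path.
#' @param designs design registry passed to \code{\link{choice_data}}.
#' @return \code{read_choice_csv} returns a \code{\link{choice_data}};
#'   \code{write_choice_csv} invisibly returns \code{path}.
#' @export
read_choice_csv <- function(path, designs = hl_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("subject_id", "task_id", "row_index", "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")))
  bad <- which(!df$response %in% RESPONSE_LEVELS)
  if (length(bad))
    stop(sprintf("%s: invalid response '%s' on data line %d",
                 path, df$response[bad[1L]], bad[1L] + 1L))
  choice_data(df, designs)
}

#' @rdname read_choice_csv
#' @param data a \code{\link{choice_data}} object.
#' @export
write_choice_csv <- function(data, path) {
  stopifnot(inherits(data, "choice_data"))
  utils::write.csv(data$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
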