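#' Construct an item bank
#'
#' An item bank is the basic container for an ordinal symptom inventory: one
#' row per item, carrying the item's subdomain assignment, its number of
#' response categories, and (once calibrated or generated) its graded-response
#' parameters under the bifactor restriction. Each item loads on the primary
#' dimension and on exactly one group (subdomain) factor.
#'
#' @param item_id character vector of unique item identifiers.
#' @param subdomain character vector assigning each item to one subdomain.
#' @param n_categories integer vector (>= 2), number of ordinal response
#'   categories per item (codes run `0 .. n_categories - 1`).
#' @param a0 optional numeric vector of primary-dimension slopes (>= 0 under
#'   the sign convention used throughout); `NA` marks an uncalibrated item.
#' @param ag optional numeric vector of group-factor slopes.
#' @param thresholds optional list of numeric vectors; element `j` holds the
#'   `n_categories[j] - 1` strictly increasing category thresholds of item `j`.
#' @param stem optional character vector of item stems (metadata only).
#'
#' @return A data frame of class `item_bank` with columns `item_id`,
#'   `subdomain`, `n_categories`, `a0`, `ag`, `thresholds` (list column) and
#'   optionally `stem`.
#' @export
#' @examples
#' bank <- item_bank(
#'   item_id = c("i1", "i2"), subdomain = c("intrusion", "avoidance"),
#'   n_categories = c(4, 5)
#' )
item_bank <- function(item_id, subdomain, n_categories,
                      a0 = NULL, ag = NULL, thresholds = NULL, stem = NULL) {
  item_id <- as.character(item_id)
  subdomain <- as.character(subdomain)
  n_categories <- as.integer(n_categories)
  n <- length(item_id)
  if (length(subdomain) != n || length(n_categories) != n) {
    stop("item_id, subdomain and n_categories must have equal length")
  }
  if (anyDuplicated(item_id)) {
    stop("duplicate item_id in bank: ",
         paste(unique(item_id[duplicated(item_id)]), collapse = ", "))
  }
  if (any(n_categories < 2L)) stop("n_categories must be >= 2 for every item")
  if (is.null(a0)) a0 <- rep(NA_real_, n)
  if (is.null(ag)) ag <- rep(NA_real_, n)
  if (is.null(thresholds)) thresholds <- rep(list(NULL), n)
  bank <- data.frame(
    item_id = item_id, subdomain = subdomain, n_categories = n_categories,
    a0 = as.numeric(a0), ag = as.numeric(ag),
    stringsAsFactors = FALSE
  )
  bank$thresholds <- thresholds
  if (!is.null(stem)) bank$stem <- as.character(stem)
  class(bank) <- c("item_bank", "data.frame")
  validate_bank(bank)
  bank
}

#' Validate an item bank
#'
#' Checks structural invariants: unique ids, `n_categories >= 2`, and for
#' every calibrated item a nonnegative primary slope and strictly increasing
#' thresholds of length `n_categories - 1`.
#'
#' @param bank an `item_bank`.
#' @param require_calibrated if `TRUE`, every item must carry parameters.
#' @return the bank, invisibly; errors name the offending item.
#' @export
validate_bank <- function(bank, require_calibrated = FALSE) {
  stopifnot(is.data.frame(bank))
  needed <- c("item_id", "subdomain", "n_categories", "a0", "ag", "thresholds")
  missing_cols <- setdiff(needed, names(bank))
  if (length(missing_cols)) {
    stop("bank is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(bank$item_id)) stop("duplicate item_id in bank")
  if (any(bank$n_categories < 2L)) stop("n_categories must be >= 2")
  for (j in seq_len(nrow(bank))) {
    cal <- is_calibrated_row(bank, j)
    if (!cal) {
      if (require_calibrated) {
        stop("item '", bank$item_id[j], "' is not calibrated")
      }
      next
    }
    cv <- bank$thresholds[[j]]
    if (length(cv) != bank$n_categories[j] - 1L) {
      stop("item '", bank$item_id[j], "': expected ",
           bank$n_categories[j] - 1L, " thresholds, got ", length(cv))
    }
    if (any(diff(cv) <= 0)) {
      stop("item '", bank$item_id[j], "': thresholds must be strictly increasing")
    }
    if (is.na(bank$a0[j]) || bank$a0[j] < 0) {
      stop("item '", bank$item_id[j], "': primary slope must be >= 0")
    }
  }
  invisible(bank)
}

is_calibrated_row <- function(bank, j) {
  !is.na(bank$a0[j]) && !is.null(bank$thresholds[[j]]) &&
    length(bank$thresholds[[j]]) > 0
}

#' Is every item in the bank calibrated?
#' @param bank an `item_bank`.
#' @return logical scalar.
#' @export
bank_is_calibrated <- function(bank) {
  all(vapply(seq_len(nrow(bank)), function(j) is_calibrated_row(bank, j), TRUE))
}

#' Validate a response matrix against a bank
#'
#' Responses are an integer matrix, persons in rows and items in columns,
#' with ordinal codes `0 .. k-1` and `NA` for missing. Column names must match
#' the bank's item ids; every retained row must contain at least one observed
#' response.
#'
#' @param responses integer matrix (persons x items).
#' @param bank an `item_bank` whose items are the columns of `responses`.
#' @return the matrix, invisibly; errors name the offending cell.
#' @export
validate_responses <- function(responses, bank) {
  if (!is.matrix(responses)) stop("responses must be a matrix")
  if (is.null(colnames(responses))) stop("responses must have item ids as colnames")
  if (!all(colnames(responses) %in% bank$item_id)) {
    bad <- setdiff(colnames(responses), bank$item_id)
    stop("response columns not in bank: ", paste(bad, collapse = ", "))
  }
  kmax <- bank$n_categories[match(colnames(responses), bank$item_id)]
  for (j in seq_len(ncol(responses))) {
    y <- responses[, j]
    bad <- which(!is.na(y) & (y < 0 | y >= kmax[j] | y != floor(y)))
    if (length(bad)) {
      stop("invalid code ", y[bad[1]], " for item '", colnames(responses)[j],
           "' (", kmax[j], " categories) at row ", bad[1])
    }
  }
  empty <- which(rowSums(!is.na(responses)) == 0L)
  if (length(empty)) {
    stop("rows with no observed responses: ", paste(empty, collapse = ", "))
  }
  invisible(responses)
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank: ", nrow(x), " items, ",
      length(unique(x$subdomain)), " subdomains (",
      paste(names(table(x$subdomain)), table(x$subdomain),
            sep = ":", collapse = ", "), ")\n", sep = "")
  cat(if (bank_is_calibrated(x)) "All items calibrated.\n"
      else "Contains uncalibrated items.\n")
  invisible(x)
}
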