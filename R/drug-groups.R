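#' Define a drug group by ATC prefixes
#'
#' A drug group is a named set of ATC prefixes; a dispensing belongs to the
#' group when its full ATC code starts with any of the prefixes. Prefixes
#' may be full 7-character codes (single substances) or truncations
#' (therapeutic groups, e.g. `"C07"` for betablockers).
#'
#' @param name group label used in output tables.
#' @param prefixes non-empty character vector of ATC prefixes.
#' @return An object of class `drug_group`.
#' @examples
#' bb <- drug_group("betablockers", "C07")
#' match_group("C07AB02", bb)   # metoprolol: TRUE
#' match_group("C08DA01", bb)   # verapamil: FALSE
#' @export
drug_group <- function(name, prefixes) {
  prefixes <- as.character(prefixes)
  if (length(prefixes) == 0 || any(!nzchar(prefixes)))
    stop("a drug group needs at least one non-empty ATC prefix")
  structure(list(name = name, prefixes = prefixes), class = "drug_group")
}

#' @export
print.drug_group <- function(x, ...) {
  cat(sprintf("Drug group '%s': ATC %s\n", x$name,
              paste(x$prefixes, collapse = ", ")))
  invisible(x)
}

#' @rdname drug_group
#' @param atc_code character vector of ATC codes. Full codes must follow
#'   ATC syntax (letter, two digits, two letters, two digits); shorter
#'   strings must be a syntactically valid truncation.
#' @param group a `drug_group`.
#' @return `match_group()`: logical vector, `TRUE` where the code belongs
#'   to the group.
#' @export
match_group <- function(atc_code, group) {
  stopifnot(inherits(group, "drug_group"))
  bad <- !is_valid_atc(atc_code)
  if (any(bad))
    stop("malformed ATC code(s): ", paste(unique(atc_code[bad]), collapse = ", "))
  Reduce(`|`, lapply(group$prefixes, function(p) startsWith(atc_code, p)))
}

#' Validate ATC code syntax
#'
#' Accepts a full 7-character ATC code (`A02BC02` pattern: letter, two
#' digits, two letters, two digits) or any leading truncation at the
#' standard classification levels (1, 3, 4, 5 or 7 characters).
#'
#' @param atc_code character vector.
#' @return Logical vector.
#' @export
is_valid_atc <- function(atc_code) {
  grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", atc_code)
}

#' Drug groups studied around AChEI initiation
#'
#' The five single drug groups with heart-rate or QT-interval relevance
#' monitored around AChEI initiation: haloperidol (N05AD01),
#' citalopram/escitalopram (N06AB10, N06AB04), verapamil (C08DA01),
#' betablockers (C07) and digitalis glycosides digitoxin/digoxin (C01A).
#'
#' @return Named list of [drug_group()] objects.
#' @export
default_drug_groups <- function() {
  groups <- list(
    drug_group("haloperidol", "N05AD01"),
    drug_group("citalopram_escitalopram", c("N06AB10", "N06AB04")),
    drug_group("verapamil", "C08DA01"),
    drug_group("betablockers", "C07"),
    drug_group("digitalis", "C01A")
  )
  names(groups) <- vapply(groups, `[[`, character(1), "name")
  groups
}

#' @rdname default_drug_groups
#' @return `default_combinations()`: list of two-element lists of
#'   [drug_group()]s — the concomitant-use pairs studied (betablockers with
#'   citalopram/escitalopram, and verapamil with citalopram/escitalopram).
#' @export
default_combinations <- function() {
  g <- default_drug_groups()
  list(
    betablockers_citalopram_escitalopram =
      list(g$betablockers, g$citalopram_escitalopram),
    verapamil_citalopram_escitalopram =
      list(g$verapamil, g$citalopram_escitalopram)
  )
}

#' AChEI drug group (ATC N06DA)
#'
#' @return A [drug_group()] covering all acetylcholinesterase inhibitors.
#' @export
achei_group <- function() drug_group("achei", "N06DA")
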