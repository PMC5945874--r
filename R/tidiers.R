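#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy cleavage calls
#' @param x A `cleavage_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble of calls.
#' @method tidy cleavage_calls
#' @export
tidy.cleavage_calls <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' One-row summary of a cleavage scan
#' @param x A `cleavage_calls` tibble.
#' @param ... Unused.
#' @return Tibble with n_sites, max_score, cutoff.
#' @method glance cleavage_calls
#' @export
glance.cleavage_calls <- function(x, ...) {
  params <- attr(x, "params")
  tibble(n_sites = nrow(x),
         max_score = if (nrow(x)) max(x$score) else NA_real_,
         cutoff = params$cutoff %||% NA_real_)
}

#' Tidy an indel summary (ranked mutant patterns)
#' @param x An `indel_summary`.
#' @param ... Unused.
#' @return The ranked pattern tibble.
#' @method tidy indel_summary
#' @export
tidy.indel_summary <- function(x, ...) x$patterns

#' One-row amplicon editing summary
#' @param x An `indel_summary`.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @method glance indel_summary
#' @export
glance.indel_summary <- function(x, ...) x$summary

#' @export
print.indel_summary <- function(x, ...) {
  cat("<indel_summary>\n")
  print(x$summary)
  if (nrow(x$patterns)) {
    cat("top patterns:\n")
    print(utils::head(x$patterns, 5))
  }
  invisible(x)
}

unclass_keep_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("cleavage_calls", "end_pileup",
                                  "guide_target"))
  attr(x, "params") <- NULL
  x
}
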