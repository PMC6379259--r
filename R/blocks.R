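#' Session block design
#'
#' The practice session is 20 bowing trials split into four blocks of five:
#' a baseline block (trials 1-5, before any feedback or video review is
#' available) and three learning blocks. The baseline block is the reference
#' interval both for Sound-instability percent change and for ERD/ERS.
#'
#' @param baseline,early,middle,late Integer vectors of trial indices.
#' @return An object of class `block_design`: a named list of disjoint trial
#'   index vectors whose union covers trials 1-20 (for the default design).
#' @examples
#' block_design()
#' @export
block_design <- function(baseline = 1:5, early = 6:10, middle = 11:15,
                         late = 16:20) {
  bd <- list(baseline = as.integer(baseline), early = as.integer(early),
             middle = as.integer(middle), late = as.integer(late))
  all_trials <- unlist(bd, use.names = FALSE)
  if (anyDuplicated(all_trials))
    stop("block design has overlapping trial ranges", call. = FALSE)
  structure(bd, class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block design (trials):\n")
  for (b in names(x))
    cat(sprintf("  %-8s %s\n", b, paste(range(x[[b]]), collapse = "-")))
  invisible(x)
}

#' Map trial indices to block names
#'
#' @param trial Integer vector of trial indices.
#' @param design A [block_design()].
#' @return Character vector of block names (`NA` for trials outside the
#'   design).
#' @export
block_of_trial <- function(trial, design = block_design()) {
  out <- rep(NA_character_, length(trial))
  for (b in names(design)) out[trial %in% design[[b]]] <- b
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
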