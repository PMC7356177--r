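#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data :=
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   distinct bind_rows left_join rename n across desc row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl map2 map2_lgl pmap imap
#' @importFrom ggplot2 scale_fill_manual
#' @importFrom stats pt phyper p.adjust rnorm runif setNames
#' @importFrom utils head modifyList
NULL

# locale-independent character sort, used for every deterministic tie-break
sort_c <- function(x) x[order(x, method = "radix")]

order_c <- function(...) order(..., method = "radix")

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from one root seed. Independent
#' stages (cohort, network, regulatory annotation, gene sets) draw from
#' child seeds obtained by this rule so that adding a stage never perturbs
#' the stream of another.
#'
#' @param seed Integer root seed.
#' @param stream Small integer stream index (>= 1).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  as.integer((abs(seed) * 101L + stream * 7919L) %% (2^31 - 1))
}

lnc_abort <- function(msg, class) {
  abort(msg, class = c(class, "lncnet_error"))
}

format_error <- function(msg) lnc_abort(msg, "lncnet_format_error")
config_error <- function(msg) lnc_abort(msg, "lncnet_config_error")
parameter_error <- function(msg) lnc_abort(msg, "lncnet_parameter_error")
analysis_error <- function(msg) lnc_abort(msg, "lncnet_analysis_error")

# sort module labels M1, M2, ... by their numeric suffix
sort_module_labels <- function(labels) {
  if (length(labels) == 0) return(character(0))
  suf <- suppressWarnings(as.numeric(sub("^M", "", labels)))
  if (anyNA(suf)) return(sort_c(labels))
  labels[order(suf)]
}
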