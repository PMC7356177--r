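# The lncRNA prioritization cascade: among modulated lncRNAs, keep those with
# |FC| >= 4 and validated miRNA targets, resolve lncRNA->miRNA->gene chains
# (plus direct lncRNA->gene interactions) against the coding DEG set, drop
# lncRNAs with no DEG targets, compute module coverage, and prioritize the
# lncRNAs whose targets reach every detected module.

#' Filter lncRNA records by fold-change magnitude
#'
#' Retains records with `|fc| >= fc_min` (inclusive: "above or equal").
#'
#' @param lnc_degs A `deg_results` tibble (lncRNA-class selected records).
#' @param fc_min Minimum absolute linear fold change (default 4).
#' @return The retained rows.
#' @export
filter_by_fc <- function(lnc_degs, fc_min = 4) {
  filter(lnc_degs, abs(.data$fc) >= fc_min)
}

#' Keep lncRNAs with at least one validated miRNA interaction
#'
#' @param lncs Character vector of lncRNA ids.
#' @param annotation A [regulatory_annotation()].
#' @return The subset of `lncs` present in the lncRNA-miRNA pair table.
#' @export
require_validated_mirnas <- function(lncs, annotation) {
  stopifnot(inherits(annotation, "regulatory_annotation"))
  lncs[lncs %in% annotation$lnc_mirna$lnc_id]
}

#' Resolve the targets of one lncRNA
#'
#' `targeted_mirnas` are the miRNAs the lncRNA interacts with;
#' `targeted_degs` are the genes it reaches either directly (lncRNA-gene
#' pairs) or through any targeted miRNA (miRNA-gene pairs), intersected with
#' the coding DEG set. A gene reached both ways counts once.
#'
#' @param lnc A single lncRNA id.
#' @param annotation A [regulatory_annotation()].
#' @param coding_degs Character vector of coding DEG symbols.
#' @return List with character vectors `targeted_mirnas` and `targeted_degs`.
#' @export
resolve_targets <- function(lnc, annotation, coding_degs) {
  stopifnot(length(lnc) == 1, inherits(annotation, "regulatory_annotation"))
  mirnas <- sort_c(unique(
    annotation$lnc_mirna$mirna_id[annotation$lnc_mirna$lnc_id == lnc]
  ))
  direct <- annotation$lnc_gene$gene[annotation$lnc_gene$lnc_id == lnc]
  via_mirna <- annotation$mirna_gene$gene[annotation$mirna_gene$mirna_id %in% mirnas]
  degs <- sort_c(intersect(unique(c(direct, via_mirna)), coding_degs))
  list(targeted_mirnas = mirnas, targeted_degs = degs)
}

#' Build lncRNA priority records
#'
#' One record per lncRNA-class selected DEG, with resolved targets and the
#' cascade pass flags (`passed_fc`, `passed_mirna`, `passed_deg`). Coverage
#' columns are filled by [module_coverage()].
#'
#' @param lnc_degs A `deg_results` tibble restricted to selected lncRNAs.
#' @param annotation A [regulatory_annotation()].
#' @param coding_degs Character vector of coding DEG symbols.
#' @param fc_min Fold-change gate for `passed_fc` (default 4).
#' @return A tibble of class `lnc_priority` with list-columns
#'   `targeted_mirnas`, `targeted_degs` and logical pass flags.
#' @export
build_lnc_records <- function(lnc_degs, annotation, coding_degs, fc_min = 4) {
  ids <- lnc_degs$feature_id
  targets <- map(ids, resolve_targets, annotation = annotation,
                 coding_degs = coding_degs)
  res <- tibble(
    lnc_id = ids,
    fc = lnc_degs$fc,
    targeted_mirnas = map(targets, "targeted_mirnas"),
    targeted_degs = map(targets, "targeted_degs"),
    module_associated_degs = list(character(0))[rep(1, length(ids))],
    covered_modules = list(character(0))[rep(1, length(ids))],
    passed_fc = abs(lnc_degs$fc) >= fc_min,
    passed_mirna = map_int(targets, ~ length(.x$targeted_mirnas)) > 0,
    passed_deg = map_int(targets, ~ length(.x$targeted_degs)) > 0,
    prioritized = FALSE
  )
  class(res) <- c("lnc_priority", class(res))
  res
}

#' Drop lncRNAs with no DEG targets
#'
#' @param records An `lnc_priority` tibble.
#' @return Rows whose `targeted_degs` set is non-empty.
#' @export
exclude_no_deg_targets <- function(records) {
  filter(records, map_int(.data$targeted_degs, length) > 0)
}

#' Compute module coverage for lncRNA records
#'
#' Fills `module_associated_degs` (targeted DEGs that belong to any module)
#' and `covered_modules` (labels of modules whose members intersect the
#' targeted DEGs).
#'
#' @param records An `lnc_priority` tibble.
#' @param modules A `gene_modules` tibble from [find_modules()]; must be
#'   non-empty (coverage is undefined with no modules).
#' @return `records` with the coverage columns filled.
#' @export
module_coverage <- function(records, modules) {
  if (is.null(modules) || nrow(modules) == 0) {
    analysis_error("module coverage is undefined with an empty module list")
  }
  all_members <- module_genes(modules)
  records$module_associated_degs <- map(records$targeted_degs,
                                        ~ intersect(.x, all_members))
  records$covered_modules <- map(records$targeted_degs, function(degs) {
    hit <- map_lgl(modules$members, ~ length(intersect(.x, degs)) > 0)
    sort_module_labels(modules$label[hit])
  })
  records
}

#' Prioritize lncRNAs covering every module
#'
#' A record is prioritized when its covered modules equal the full label set
#' of all detected modules (and it passed the fold-change, miRNA and
#' DEG-target gates). Returns all records, flagged, sorted by descending
#' `|fc|` with prioritized records first.
#'
#' @param records An `lnc_priority` tibble after [module_coverage()].
#' @param modules A `gene_modules` tibble, or a character vector of module
#'   labels defining the full label set directly.
#' @return `records` with `prioritized` rewritten and rows re-ordered.
#' @export
prioritize_full_coverage <- function(records, modules) {
  labels <- if (is.character(modules)) modules else modules$label
  full <- sort_module_labels(unique(labels))
  covers_all <- if (length(full) == 0) {
    rep(FALSE, nrow(records))
  } else {
    map_lgl(records$covered_modules, ~ setequal(.x, full))
  }
  records <- mutate(
    records,
    prioritized = .data$passed_fc & .data$passed_mirna & .data$passed_deg &
      covers_all
  )
  records[order(-as.integer(records$prioritized), -abs(records$fc),
                records$lnc_id, method = "radix"), ]
}

#' Run the full lncRNA prioritization cascade
#'
#' Composes [build_lnc_records()], the fold-change, miRNA and DEG-target
#' gates, [module_coverage()] and [prioritize_full_coverage()]. All records
#' are returned with their pass flags (nothing is silently dropped), so the
#' funnel at each gate can be read off the flags.
#'
#' @param lnc_degs A `deg_results` tibble restricted to selected lncRNA
#'   records.
#' @param annotation A [regulatory_annotation()].
#' @param coding_degs Character vector of coding DEG symbols.
#' @param modules A `gene_modules` tibble.
#' @param fc_min Fold-change gate (default 4).
#' @return An `lnc_priority` tibble.
#' @export
prioritize_lncrnas <- function(lnc_degs, annotation, coding_degs, modules,
                               fc_min = 4) {
  records <- build_lnc_records(lnc_degs, annotation, coding_degs,
                               fc_min = fc_min)
  if (nrow(records) == 0) return(records)
  records <- module_coverage(records, modules)
  prioritize_full_coverage(records, modules)
}

#' Render the priority table
#'
#' One row per lncRNA with the counts of targeted miRNAs, targeted DEGs and
#' module-associated targeted DEGs, plus the space-joined sorted module
#' labels. Empty sets render as `"none"`.
#'
#' @param records An `lnc_priority` tibble.
#' @return A tibble with character columns `lnc_id`, `fc`,
#'   `targeted_mirnas`, `targeted_degs`, `module_associated_degs`,
#'   `targeted_modules`.
#' @export
render_priority_table <- function(records) {
  count_or_none <- function(sets) {
    n <- map_int(sets, length)
    ifelse(n == 0, "none", as.character(n))
  }
  tibble(
    lnc_id = records$lnc_id,
    fc = as.character(round(records$fc, 2)),
    targeted_mirnas = count_or_none(records$targeted_mirnas),
    targeted_degs = count_or_none(records$targeted_degs),
    module_associated_degs = count_or_none(records$module_associated_degs),
    targeted_modules = map_chr(records$covered_modules, function(m) {
      if (length(m) == 0) "none" else paste(m, collapse = " ")
    })
  )
}

#' Encode an already-tabulated candidate table as priority records
#'
#' For worked examples where a published candidate table (fold changes,
#' per-column counts and covered-module labels) is the input rather than raw
#' annotation: builds an `lnc_priority` tibble directly from the table so the
#' coverage rule can be applied to it.
#'
#' @param tbl Tibble with columns `lnc_id`, `fc`, `n_mirnas`, `n_degs`,
#'   `n_module_degs`, `modules` (space-separated labels or `"none"`).
#' @param fc_min Fold-change gate (default 4).
#' @return An `lnc_priority` tibble (target sets are placeholder identifiers
#'   sized to the published counts).
#' @export
as_lnc_priority <- function(tbl, fc_min = 4) {
  tbl <- as_tibble(tbl)
  placeholder <- function(n, prefix, id) {
    if (n == 0) character(0) else paste0(id, ":", prefix, seq_len(n))
  }
  res <- tibble(
    lnc_id = as.character(tbl$lnc_id),
    fc = as.numeric(tbl$fc),
    targeted_mirnas = map2(tbl$n_mirnas, tbl$lnc_id,
                           ~ placeholder(.x, "miR", .y)),
    targeted_degs = map2(tbl$n_degs, tbl$lnc_id, ~ placeholder(.x, "g", .y)),
    module_associated_degs = map2(tbl$n_module_degs, tbl$lnc_id,
                                  ~ placeholder(.x, "mg", .y)),
    covered_modules = map(tbl$modules, function(m) {
      if (is.na(m) || m == "none" || m == "") character(0)
      else sort_module_labels(strsplit(m, "[ ,]+")[[1]])
    }),
    passed_fc = abs(as.numeric(tbl$fc)) >= fc_min,
    passed_mirna = tbl$n_mirnas > 0,
    passed_deg = tbl$n_degs > 0,
    prioritized = FALSE
  )
  class(res) <- c("lnc_priority", class(res))
  res
}
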