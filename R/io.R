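# Readers and writers for every external table the pipeline touches.
# Dialect: UTF-8, tab-separated, one header row, '#'-prefixed comment lines.

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) {
    lnc_abort(paste0("file not found: ", path), "lncnet_io_error")
  }
  readr::read_tsv(path, col_types = col_types, comment = "#", progress = FALSE)
}

#' Construct an expression set
#'
#' Container for a normalized, log2-scale expression matrix together with the
#' sample group labels (case/control) and feature classes (coding/lncRNA).
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique dimnames.
#' @param groups Tibble with columns `sample_id`, `group` (values `case` or
#'   `control`).
#' @param classes Tibble with columns `feature_id`, `class` (values `coding`
#'   or `lncRNA`).
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(values, groups, classes) {
  if (!is.matrix(values) || !is.numeric(values)) {
    format_error("expression values must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    format_error("expression matrix must have feature and sample names")
  }
  if (anyDuplicated(fid)) {
    format_error(paste0("duplicate feature id: ", fid[duplicated(fid)][1]))
  }
  if (anyDuplicated(sid)) {
    format_error(paste0("duplicate sample id: ", sid[duplicated(sid)][1]))
  }
  groups <- as_tibble(groups)
  classes <- as_tibble(classes)
  stopifnot(all(c("sample_id", "group") %in% names(groups)),
            all(c("feature_id", "class") %in% names(classes)))
  missing_s <- setdiff(sid, groups$sample_id)
  if (length(missing_s) > 0) {
    format_error(paste0("sample missing from groups table: ", missing_s[1]))
  }
  if (!all(groups$group %in% c("case", "control"))) {
    format_error("group labels must be 'case' or 'control'")
  }
  missing_f <- setdiff(fid, classes$feature_id)
  if (length(missing_f) > 0) {
    format_error(paste0("feature missing from classes table: ", missing_f[1]))
  }
  if (!all(classes$class %in% c("coding", "lncRNA"))) {
    format_error("feature classes must be 'coding' or 'lncRNA'")
  }
  grp <- setNames(groups$group, groups$sample_id)[sid]
  if (!all(c("case", "control") %in% grp)) {
    format_error("both case and control groups must be non-empty")
  }
  cls <- setNames(classes$class, classes$feature_id)[fid]
  structure(
    list(values = values, groups = grp, classes = cls),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf(
    "<expr_set> %d features (%d coding, %d lncRNA) x %d samples (%d case, %d control)\n",
    nrow(x$values), sum(x$classes == "coding"), sum(x$classes == "lncRNA"),
    ncol(x$values), sum(x$groups == "case"), sum(x$groups == "control")
  ))
  invisible(x)
}

#' @method as_tibble expr_set
#' @export
as_tibble.expr_set <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values),
    group = rep(unname(x$groups), each = nrow(x$values)),
    class = rep(unname(x$classes), times = ncol(x$values))
  )
}

#' Read an expression matrix with its group and class tables
#'
#' The matrix file is a TSV whose header row holds sample ids and whose first
#' column holds feature ids; `groups_path` maps `sample_id` to `case`/
#' `control` and `classes_path` maps `feature_id` to `coding`/`lncRNA`.
#'
#' @param matrix_path,groups_path,classes_path File paths.
#' @return An [expr_set()].
#' @export
read_expression <- function(matrix_path, groups_path, classes_path) {
  mat_tbl <- read_tsv_strict(matrix_path, readr::cols(.default = readr::col_character()))
  if (ncol(mat_tbl) < 2) format_error("expression matrix needs >= 1 sample column")
  fid <- mat_tbl[[1]]
  vals <- as.matrix(mat_tbl[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    format_error(sprintf(
      "non-numeric expression value at feature '%s', sample '%s'",
      fid[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  rownames(num) <- fid
  groups <- read_tsv_strict(groups_path,
                            readr::cols(sample_id = "c", group = "c"))
  classes <- read_tsv_strict(classes_path,
                             readr::cols(feature_id = "c", class = "c"))
  expr_set(num, groups, classes)
}

#' Write an expression set to the pipeline's TSV dialect
#'
#' @param x An [expr_set()].
#' @param matrix_path,groups_path,classes_path Output paths.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, matrix_path, groups_path, classes_path) {
  stopifnot(inherits(x, "expr_set"))
  tbl <- bind_cols_matrix(x$values)
  readr::write_tsv(tbl, matrix_path, progress = FALSE)
  readr::write_tsv(tibble(sample_id = names(x$groups), group = unname(x$groups)),
                   groups_path, progress = FALSE)
  readr::write_tsv(tibble(feature_id = names(x$classes), class = unname(x$classes)),
                   classes_path, progress = FALSE)
  invisible(x)
}

bind_cols_matrix <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  tibble(feature_id = rownames(m)) |> dplyr::bind_cols(out)
}

#' Read a STRING-style interaction edge list
#'
#' The file is a TSV with columns `protein_a`, `protein_b`,
#' `experimental_score` (scores in `[0, 1]`). Self-loops are dropped,
#' duplicate and reciprocal rows collapse to one undirected edge keeping the
#' maximum score, and edges scoring below `min_score` are excluded.
#'
#' @param path File path.
#' @param min_score Minimum evidence score to retain an edge (default 0.4).
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, min_score = 0.4) {
  stopifnot(is.numeric(min_score), min_score >= 0, min_score <= 1)
  tbl <- read_tsv_strict(path, readr::cols(
    protein_a = "c", protein_b = "c", experimental_score = "c"
  ))
  if (!all(c("protein_a", "protein_b", "experimental_score") %in% names(tbl))) {
    format_error("edge list must have columns protein_a, protein_b, experimental_score")
  }
  if (nrow(tbl) == 0) return(ppi_network(edges = empty_edges()))
  bad_row <- which(is.na(tbl$protein_a) | is.na(tbl$protein_b) |
                     tbl$protein_a == "" | tbl$protein_b == "")
  if (length(bad_row) > 0) {
    format_error(sprintf("malformed edge row at line %d", bad_row[1] + 1L))
  }
  score <- suppressWarnings(as.numeric(tbl$experimental_score))
  bad <- which(is.na(score))
  if (length(bad) > 0) {
    format_error(sprintf("malformed edge row at line %d (non-numeric score)", bad[1] + 1L))
  }
  if (any(score < 0 | score > 1)) {
    format_error("edge score outside [0, 1]")
  }
  edges <- tibble(from = tbl$protein_a, to = tbl$protein_b, score = score)
  ppi_network(edges = edges, min_score = min_score)
}

#' Write a network as a STRING-style edge list
#'
#' @param network A [ppi_network()].
#' @param path Output path.
#' @return `network`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  readr::write_tsv(
    tibble(protein_a = network$edges$from, protein_b = network$edges$to,
           experimental_score = network$edges$score),
    path, progress = FALSE
  )
  invisible(network)
}

#' Read regulatory annotation tables
#'
#' Three two-column TSVs of id pairs: validated lncRNA–miRNA interactions,
#' direct lncRNA–gene interactions, and miRNA–gene target lists. An optional
#' third `evidence` column is checked against `accepted_evidence`; rows with
#' other labels are dropped (a message reports the count). Duplicate pairs
#' are removed.
#'
#' @param lnc_mirna_path,lnc_gene_path,mirna_gene_path File paths.
#' @param accepted_evidence Character vector of evidence labels to keep, or
#'   `NULL` to accept everything.
#' @return A `regulatory_annotation`: list of tibbles `lnc_mirna`
#'   (`lnc_id`, `mirna_id`), `lnc_gene` (`lnc_id`, `gene`), `mirna_gene`
#'   (`mirna_id`, `gene`).
#' @export
read_regulatory <- function(lnc_mirna_path, lnc_gene_path, mirna_gene_path,
                            accepted_evidence = NULL) {
  read_pairs <- function(path, nms) {
    tbl <- read_tsv_strict(path, readr::cols(.default = readr::col_character()))
    if (nrow(tbl) > 0 && ncol(tbl) < 2) {
      format_error(paste0("pair table needs >= 2 columns: ", path))
    }
    if (nrow(tbl) == 0) {
      return(tibble(!!nms[1] := character(0), !!nms[2] := character(0)))
    }
    if (any(is.na(tbl[[1]]) | is.na(tbl[[2]]) | tbl[[1]] == "" | tbl[[2]] == "")) {
      format_error(paste0("empty identifier in pair table: ", path))
    }
    if (!is.null(accepted_evidence) && ncol(tbl) >= 3) {
      keep <- tbl[[3]] %in% accepted_evidence
      if (any(!keep)) {
        inform(sprintf("%s: dropped %d rows with unaccepted evidence labels",
                       basename(path), sum(!keep)))
      }
      tbl <- tbl[keep, , drop = FALSE]
    }
    out <- tibble(!!nms[1] := tbl[[1]], !!nms[2] := tbl[[2]])
    distinct(out)
  }
  structure(
    list(
      lnc_mirna = read_pairs(lnc_mirna_path, c("lnc_id", "mirna_id")),
      lnc_gene = read_pairs(lnc_gene_path, c("lnc_id", "gene")),
      mirna_gene = read_pairs(mirna_gene_path, c("mirna_id", "gene"))
    ),
    class = "regulatory_annotation"
  )
}

#' Assemble a regulatory annotation from in-memory pair tables
#'
#' @param lnc_mirna,lnc_gene,mirna_gene Two-column data frames of id pairs
#'   (`lnc_id`/`mirna_id`, `lnc_id`/`gene`, `mirna_id`/`gene`).
#' @return A `regulatory_annotation`.
#' @export
regulatory_annotation <- function(lnc_mirna = NULL, lnc_gene = NULL,
                                  mirna_gene = NULL) {
  canon <- function(x, nms) {
    if (is.null(x) || nrow(as_tibble(x)) == 0) {
      return(tibble(!!nms[1] := character(0), !!nms[2] := character(0)))
    }
    x <- as_tibble(x)
    out <- tibble(!!nms[1] := as.character(x[[1]]), !!nms[2] := as.character(x[[2]]))
    if (any(out[[1]] == "" | out[[2]] == "")) {
      format_error("empty identifier in regulatory pair")
    }
    distinct(out)
  }
  structure(
    list(
      lnc_mirna = canon(lnc_mirna, c("lnc_id", "mirna_id")),
      lnc_gene = canon(lnc_gene, c("lnc_id", "gene")),
      mirna_gene = canon(mirna_gene, c("mirna_id", "gene"))
    ),
    class = "regulatory_annotation"
  )
}

#' @export
print.regulatory_annotation <- function(x, ...) {
  cat(sprintf(
    "<regulatory_annotation> %d lncRNA-miRNA, %d lncRNA-gene, %d miRNA-gene pairs\n",
    nrow(x$lnc_mirna), nrow(x$lnc_gene), nrow(x$mirna_gene)
  ))
  invisible(x)
}

write_pairs <- function(tbl, path) readr::write_tsv(tbl, path, progress = FALSE)

#' Write regulatory annotation tables
#' @param annotation A `regulatory_annotation`.
#' @param lnc_mirna_path,lnc_gene_path,mirna_gene_path Output paths.
#' @return `annotation`, invisibly.
#' @export
write_regulatory <- function(annotation, lnc_mirna_path, lnc_gene_path,
                             mirna_gene_path) {
  write_pairs(annotation$lnc_mirna, lnc_mirna_path)
  write_pairs(annotation$lnc_gene, lnc_gene_path)
  write_pairs(annotation$mirna_gene, mirna_gene_path)
  invisible(annotation)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...` (>= 3 fields). Duplicate members
#' within a set are collapsed. The universe defaults to the union of all
#' members unless supplied.
#'
#' @param path GMT file path.
#' @param universe Optional character vector of gene symbols defining the
#'   test universe; defaults to the union of all set members.
#' @return A `geneset_collection`: list with `sets` (named list of character
#'   vectors) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) lnc_abort(paste0("file not found: ", path), "lncnet_io_error")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      format_error(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      format_error(paste0("duplicate gene-set name: ", nm))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[nm]] <- members
  }
  geneset_collection(sets, universe)
}

#' Assemble a gene-set collection
#'
#' @param sets Named list of character vectors (gene symbols). Every set must
#'   be non-empty; members need not all lie in the universe (membership is
#'   intersected at test time).
#' @param universe Character vector, or `NULL` to default to the union of all
#'   set members.
#' @return A `geneset_collection`.
#' @export
geneset_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    format_error("gene sets must be named")
  }
  if (any(map_int(sets, length) == 0)) {
    format_error("every gene set must be non-empty")
  }
  sets <- map(sets, ~ sort_c(unique(as.character(.x))))
  if (is.null(universe)) {
    universe <- sort_c(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort_c(unique(as.character(universe)))
  }
  structure(list(sets = sets, universe = universe), class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection A `geneset_collection`.
#' @param path Output path.
#' @return `collection`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- imap(collection$sets, function(members, nm) {
    paste(c(nm, "na", members), collapse = "\t")
  })
  readr::write_lines(unlist(lines), path)
  invisible(collection)
}
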