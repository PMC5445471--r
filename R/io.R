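# Tab-delimited input/output and cross-gene consistency validation.

# Cq cell encodings that mean "no amplification signal observed".
UNDETECTED_TOKENS <- c("", "NA", "Undetermined", "999")

GENE_TABLE_HEADER <- c("sample", "dilution", "replicate", "cq", "rel_quantity")
STANDARD_TABLE_HEADER <- c("quantity", "cq")

# full-precision numeric formatting so serialize -> parse round-trips exactly
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

.read_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (length(input) == 1L && grepl("\n", input)) {
    strsplit(input, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(input)
  }
}

.split_tsv <- function(lines) {
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  strsplit(lines[keep], "\t", fixed = TRUE)
}

#' Parse a per-gene table of sample reactions
#'
#' Reads the five-column tab-delimited gene table (header
#' \code{sample  dilution  replicate  cq  rel_quantity}; one row per qPCR
#' well) into a gene assay. Cq cells that are empty, \code{"NA"},
#' \code{"Undetermined"} or \code{"999"} are treated as undetected
#' (no amplification signal) and stored as \code{NA}.
#'
#' @param input Path to a TSV file, a single string containing the TSV text,
#'   or a character vector of lines.
#' @param gene_id Gene/assay identifier.
#' @param role Either \code{"target"} or \code{"reference"}.
#' @param import_order Position of this gene among the reference genes
#'   (1 = imported first; reference-gene scaling uses the first-imported
#'   gene as the anchor). Ignored for targets.
#' @return An object of class \code{gene_assay}: a list with
#'   \code{gene_id}, \code{role}, \code{import_order}, \code{n_dilutions}
#'   and a \code{reactions} data frame (\code{sample}, \code{dilution},
#'   \code{replicate}, \code{cq}, \code{rel_quantity}).
#' @examples
#' txt <- paste(
#'   "sample\tdilution\treplicate\tcq\trel_quantity",
#'   "S1\t1\t1\t24.1\t1",
#'   "S1\t1\t2\t24.3\t1",
#'   "S1\t2\t1\t27.5\t0.1",
#'   "S1\t2\t2\t27.4\t0.1",
#'   sep = "\n")
#' parse_gene_table(txt, "PR1b", "target")
#' @export
parse_gene_table <- function(input, gene_id, role = c("target", "reference"),
                             import_order = NA_integer_) {
  role <- match.arg(role)
  lines <- .read_lines(input)
  cells <- .split_tsv(lines)
  if (length(cells) < 2L)
    stop("gene table for '", gene_id, "' has no data rows")
  header <- trimws(tolower(cells[[1L]]))
  if (!identical(header, GENE_TABLE_HEADER))
    stop("gene table for '", gene_id, "' has unexpected header: ",
         paste(cells[[1L]], collapse = " | "))

  n <- length(cells) - 1L
  sample <- character(n); dilution <- integer(n); replicate <- integer(n)
  cq <- numeric(n); rel_quantity <- numeric(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != 5L)
      stop("gene table for '", gene_id, "', line ", i + 1L,
           ": expected 5 tab-separated fields, found ", length(row))
    sample[i] <- trimws(row[1L])
    dil <- suppressWarnings(as.integer(row[2L]))
    rep_i <- suppressWarnings(as.integer(row[3L]))
    if (is.na(dil) || dil < 1L)
      stop("gene table for '", gene_id, "', line ", i + 1L,
           ": invalid dilution index '", row[2L], "'")
    if (is.na(rep_i) || rep_i < 1L)
      stop("gene table for '", gene_id, "', line ", i + 1L,
           ": invalid replicate index '", row[3L], "'")
    dilution[i] <- dil
    replicate[i] <- rep_i
    cq_cell <- trimws(row[4L])
    if (cq_cell %in% UNDETECTED_TOKENS) {
      cq[i] <- NA_real_
    } else {
      v <- suppressWarnings(as.numeric(cq_cell))
      if (is.na(v))
        stop("gene table for '", gene_id, "', line ", i + 1L,
             ": unparseable Cq '", cq_cell, "'")
      if (v <= 0 || v > 50)
        stop("BAD_VALUE: gene table for '", gene_id, "', line ", i + 1L,
             ": Cq ", v, " outside (0, 50]")
      cq[i] <- v
    }
    q <- suppressWarnings(as.numeric(trimws(row[5L])))
    if (is.na(q))
      stop("gene table for '", gene_id, "', line ", i + 1L,
           ": unparseable rel_quantity '", row[5L], "'")
    if (q <= 0)
      stop("BAD_VALUE: gene table for '", gene_id, "', line ", i + 1L,
           ": rel_quantity must be > 0, found ", q)
    rel_quantity[i] <- q
  }
  reactions <- data.frame(sample = sample, dilution = dilution,
                          replicate = replicate, cq = cq,
                          rel_quantity = rel_quantity,
                          stringsAsFactors = FALSE)
  gene_assay(gene_id, role, reactions, import_order)
}

#' Construct a gene assay from a reactions data frame
#'
#' @param gene_id Gene/assay identifier.
#' @param role \code{"target"} or \code{"reference"}.
#' @param reactions Data frame with columns \code{sample}, \code{dilution},
#'   \code{replicate}, \code{cq} (NA = undetected), \code{rel_quantity}.
#' @param import_order Position among reference genes (see
#'   \code{\link{parse_gene_table}}).
#' @return A \code{gene_assay} object.
#' @export
gene_assay <- function(gene_id, role, reactions,
                       import_order = NA_integer_) {
  stopifnot(is.data.frame(reactions),
            all(GENE_TABLE_HEADER %in% names(reactions)))
  structure(list(gene_id = as.character(gene_id),
                 role = match.arg(role, c("target", "reference")),
                 import_order = as.integer(import_order),
                 n_dilutions = length(unique(reactions$dilution)),
                 reactions = reactions[, GENE_TABLE_HEADER]),
            class = "gene_assay")
}

#' @export
print.gene_assay <- function(x, ...) {
  cat("Gene assay '", x$gene_id, "' (", x$role, ")\n", sep = "")
  cat("  ", nrow(x$reactions), " wells, ",
      length(unique(x$reactions$sample)), " samples, ",
      x$n_dilutions, " dilution(s)\n", sep = "")
  invisible(x)
}

#' Serialize a gene assay back to its tab-delimited form
#'
#' Inverse of \code{\link{parse_gene_table}}: numbers are written at full
#' precision so that parsing the output reproduces the assay exactly.
#'
#' @param assay A \code{gene_assay}.
#' @return A single string of TSV text (with header).
#' @export
serialize_gene_table <- function(assay) {
  r <- assay$reactions
  rows <- paste(r$sample, r$dilution, r$replicate,
                .fmt_num(r$cq), .fmt_num(r$rel_quantity), sep = "\t")
  paste(c(paste(GENE_TABLE_HEADER, collapse = "\t"), rows), collapse = "\n")
}

#' Parse a standard-curve table
#'
#' Reads the two-column tab-delimited standard table (header
#' \code{quantity  cq}). Quantities may be actual or relative copy numbers;
#' replicate standard wells are kept as individual points so that replicate
#' scatter contributes to the curve's R-squared.
#'
#' @param input Path, TSV string, or character vector of lines.
#' @return A data frame with columns \code{quantity}, \code{cq} and
#'   \code{included} (all \code{TRUE}; exclusion of outlier standard points
#'   is a user decision, see \code{\link{flag_standard_outliers}}).
#' @export
parse_standard_table <- function(input) {
  lines <- .read_lines(input)
  cells <- .split_tsv(lines)
  if (length(cells) < 2L) stop("standard table has no data rows")
  header <- trimws(tolower(cells[[1L]]))
  if (!identical(header, STANDARD_TABLE_HEADER))
    stop("standard table has unexpected header: ",
         paste(cells[[1L]], collapse = " | "))
  n <- length(cells) - 1L
  quantity <- numeric(n); cq <- numeric(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != 2L)
      stop("standard table line ", i + 1L,
           ": expected 2 tab-separated fields, found ", length(row))
    q <- suppressWarnings(as.numeric(trimws(row[1L])))
    v <- suppressWarnings(as.numeric(trimws(row[2L])))
    if (is.na(q) || q <= 0)
      stop("standard table line ", i + 1L, ": quantity must be > 0")
    if (is.na(v))
      stop("standard table line ", i + 1L, ": unparseable Cq '", row[2L], "'")
    quantity[i] <- q; cq[i] <- v
  }
  if (length(unique(quantity)) < 2L)
    stop("standard table needs at least 2 distinct quantities to fit a curve")
  data.frame(quantity = quantity, cq = cq, included = TRUE)
}

#' Serialize a standard table to TSV text
#' @param std Data frame with \code{quantity} and \code{cq} columns.
#' @return A single TSV string.
#' @export
serialize_standard_table <- function(std) {
  rows <- paste(.fmt_num(std$quantity), .fmt_num(std$cq), sep = "\t")
  paste(c(paste(STANDARD_TABLE_HEADER, collapse = "\t"), rows),
        collapse = "\n")
}

#' Assemble gene assays into an experiment
#'
#' The sample order of the experiment (used for all outputs) is the
#' first-appearance order in the first imported assay. Reference genes
#' receive contiguous \code{import_order} values in the order given if not
#' already set.
#'
#' @param assays List of \code{gene_assay} objects (at least one target and
#'   one reference for a quantifiable experiment).
#' @param name Experiment name.
#' @return An object of class \code{qpcr_experiment}.
#' @export
experiment <- function(assays, name = "experiment") {
  stopifnot(length(assays) >= 1L,
            all(vapply(assays, inherits, logical(1), "gene_assay")))
  ids <- vapply(assays, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(assays) <- ids
  is_ref <- vapply(assays, function(a) a$role == "reference", logical(1))
  orders <- vapply(assays, `[[`, integer(1), "import_order")
  if (any(is_ref)) {
    ro <- orders[is_ref]
    if (all(is.na(ro))) {
      k <- 0L
      for (i in which(is_ref)) { k <- k + 1L; assays[[i]]$import_order <- k }
    } else if (anyNA(ro) || anyDuplicated(ro) ||
               !setequal(ro, seq_along(ro))) {
      stop("reference import_order must be unique and contiguous (1..n)")
    }
  }
  first <- assays[[1L]]$reactions
  structure(list(name = name,
                 assays = assays,
                 n_dilutions = assays[[1L]]$n_dilutions,
                 sample_ids = unique(first$sample)),
            class = "qpcr_experiment")
}

#' @export
print.qpcr_experiment <- function(x, ...) {
  roles <- vapply(x$assays, `[[`, character(1), "role")
  cat("qPCR experiment '", x$name, "': ",
      sum(roles == "target"), " target gene(s), ",
      sum(roles == "reference"), " reference gene(s), ",
      length(x$sample_ids), " samples, ",
      x$n_dilutions, " dilution(s)\n", sep = "")
  invisible(x)
}

.issue <- function(code, gene_id, sample_id, message) {
  data.frame(code = code, gene_id = gene_id, sample_id = sample_id,
             message = message, stringsAsFactors = FALSE)
}

#' Check cross-gene consistency of an experiment
#'
#' Verifies that every assay covers the same samples with the same number
#' of dilutions and the same number of replicates per (sample, dilution),
#' guarding against copy-paste import errors. Per-assay value invariants
#' (dilution 1 must be the least diluted, i.e. carry the largest
#' \code{rel_quantity}; \code{rel_quantity} consistent within a
#' sample-dilution) are reported as \code{BAD_VALUE}.
#'
#' Discrepancies are report rows, never exceptions: an experiment is valid
#' iff the returned report has zero rows.
#'
#' @param exp A \code{qpcr_experiment}.
#' @return A data frame with columns \code{code} (one of
#'   \code{MISSING_SAMPLE}, \code{EXTRA_SAMPLE}, \code{REPLICATE_MISMATCH},
#'   \code{DILUTION_MISMATCH}, \code{BAD_VALUE}), \code{gene_id},
#'   \code{sample_id}, \code{message}.
#' @export
check_consistency <- function(exp) {
  stopifnot(inherits(exp, "qpcr_experiment"))
  issues <- list()
  ref_samples <- exp$sample_ids
  ref_structure <- NULL  # replicate counts per (sample, dilution), 1st assay

  count_reps <- function(r) {
    tab <- aggregate(replicate ~ sample + dilution, data = r, FUN = length)
    names(tab)[3L] <- "n"
    tab
  }
  first <- exp$assays[[1L]]
  ref_structure <- count_reps(first$reactions)
  ref_dils <- sort(unique(first$reactions$dilution))

  for (a in exp$assays) {
    r <- a$reactions
    smp <- unique(r$sample)
    for (s in setdiff(ref_samples, smp))
      issues[[length(issues) + 1L]] <-
        .issue("MISSING_SAMPLE", a$gene_id, s,
               paste0("sample '", s, "' absent from gene '", a$gene_id, "'"))
    for (s in setdiff(smp, ref_samples))
      issues[[length(issues) + 1L]] <-
        .issue("EXTRA_SAMPLE", a$gene_id, s,
               paste0("sample '", s, "' not present in first imported gene"))
    dils <- sort(unique(r$dilution))
    if (!identical(dils, ref_dils))
      issues[[length(issues) + 1L]] <-
        .issue("DILUTION_MISMATCH", a$gene_id, NA_character_,
               paste0("gene '", a$gene_id, "' has dilutions {",
                      paste(dils, collapse = ","), "} vs {",
                      paste(ref_dils, collapse = ","), "}"))
    tab <- count_reps(r)
    m <- merge(ref_structure, tab, by = c("sample", "dilution"),
               suffixes = c("_ref", "_this"))
    bad <- m[m$n_ref != m$n_this, , drop = FALSE]
    for (i in seq_len(nrow(bad)))
      issues[[length(issues) + 1L]] <-
        .issue("REPLICATE_MISMATCH", a$gene_id, bad$sample[i],
               paste0("gene '", a$gene_id, "' sample '", bad$sample[i],
                      "' dilution ", bad$dilution[i], ": ", bad$n_this[i],
                      " replicate(s) vs ", bad$n_ref[i], " in first gene"))
    # within-assay value invariants
    for (s in smp) {
      rs <- r[r$sample == s, , drop = FALSE]
      qs <- tapply(rs$rel_quantity, rs$dilution, function(v) v[1L])
      if (any(tapply(rs$rel_quantity, rs$dilution,
                     function(v) length(unique(v))) > 1L))
        issues[[length(issues) + 1L]] <-
          .issue("BAD_VALUE", a$gene_id, s,
                 paste0("gene '", a$gene_id, "' sample '", s,
                        "': rel_quantity differs between replicates of one dilution"))
      if (length(qs) >= 2L && any(diff(qs[order(as.integer(names(qs)))]) >= 0))
        issues[[length(issues) + 1L]] <-
          .issue("BAD_VALUE", a$gene_id, s,
                 paste0("gene '", a$gene_id, "' sample '", s,
                        "': rel_quantity must strictly decrease with dilution index"))
    }
  }
  if (length(issues) == 0L)
    return(data.frame(code = character(), gene_id = character(),
                      sample_id = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Export the final sample-by-gene result matrix
#'
#' Rows are samples in import order, columns are target genes in import
#' order. Cells hold the final normalized value, or are empty when the
#' decision support system refused a result. The parallel warnings matrix
#' (same shape) carries semicolon-joined status/warning codes so imputed
#' values can be distinguished from directly calculated ones.
#'
#' @param result A \code{quant_result} from \code{\link{quantify_experiment}}.
#' @param warnings_on Also return the warnings matrix.
#' @return A list with data frames \code{values} and (when requested)
#'   \code{warnings}; both have a \code{sample} column followed by one
#'   column per target gene.
#' @export
export_matrix <- function(result, warnings_on = TRUE) {
  stopifnot(inherits(result, "quant_result"))
  d <- result$decisions
  samples <- result$sample_ids
  genes <- result$target_genes
  val <- data.frame(sample = samples, stringsAsFactors = FALSE)
  wrn <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (g in genes) {
    dg <- d[d$gene == g, , drop = FALSE]
    idx <- match(samples, dg$sample)
    val[[g]] <- dg$value[idx]
    w <- dg$warnings[idx]
    status <- dg$status[idx]
    cell <- ifelse(is.na(w) | !nzchar(w), status, paste(status, w, sep = ";"))
    wrn[[g]] <- cell
  }
  out <- list(values = val)
  if (warnings_on) out$warnings <- wrn
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Write all result files of a run
#'
#' Writes \code{matrix.tsv}, \code{matrix_warnings.tsv}, a per-gene
#' \code{gene_<id>_detail.tsv} with all intermediate values, and
#' \code{curves.tsv} with the fitted standard-curve parameters.
#'
#' @param result A \code{quant_result}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "quant_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- export_matrix(result, warnings_on = TRUE)
  files <- character()
  p <- file.path(dir, "matrix.tsv"); .write_tsv(m$values, p); files <- c(files, p)
  p <- file.path(dir, "matrix_warnings.tsv"); .write_tsv(m$warnings, p)
  files <- c(files, p)
  for (g in names(result$details)) {
    p <- file.path(dir, paste0("gene_", g, "_detail.tsv"))
    .write_tsv(result$details[[g]], p)
    files <- c(files, p)
  }
  cv <- do.call(rbind, lapply(names(result$curves), function(g) {
    cu <- result$curves[[g]]
    data.frame(gene = g, slope = cu$slope, intercept = cu$intercept,
               r_squared = cu$r_squared,
               efficiency_percent = cu$efficiency_percent,
               n_points_used = cu$n_points_used, cq_loq = cu$cq_loq)
  }))
  p <- file.path(dir, "curves.tsv"); .write_tsv(cv, p); files <- c(files, p)
  invisible(files)
}
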