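# Plain-text "key = value" run configuration: QC thresholds plus the list
# of gene tables to import.

#' Read a run configuration file
#'
#' The configuration is plain text, one \code{key = value} per line
#' (\code{#} starts a comment). Recognized QC keys match the arguments of
#' \code{\link{qc_settings}} (\code{cq_extc}, \code{cv_max_percent},
#' \code{slope_min}, \code{slope_max}, \code{slope_diff_max},
#' \code{lod_divisor}, \code{std_replicate_dev_max}, \code{mode});
#' a per-gene Cq(LOQ) override is written \code{cq_loq.<gene_id> = <cycles>}
#' and a global one \code{cq_loq = <cycles>}. Gene tables are declared as
#' \preformatted{
#' gene.<id>.role = target|reference
#' gene.<id>.file = path/to/gene.tsv
#' gene.<id>.standard = path/to/standard.tsv
#' }
#' Reference genes receive their import order from their order of
#' appearance in the file (the first one is the scaling anchor).
#'
#' @param path Path to the configuration file.
#' @return List with \code{qc} (a \code{qc_settings}) and \code{genes}
#'   (data frame \code{gene_id}, \code{role}, \code{file},
#'   \code{standard}; zero rows when the file only sets thresholds).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("config line not of the form 'key = value': ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))

  num_keys <- c("cq_extc", "cv_max_percent", "slope_min", "slope_max",
                "slope_diff_max", "lod_divisor", "std_replicate_dev_max")
  qc_args <- list()
  loq <- numeric()
  genes <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% num_keys) {
      qc_args[[k]] <- as.numeric(v)
    } else if (k == "mode") {
      qc_args$mode <- v
    } else if (k == "cq_loq") {
      qc_args$cq_loq_global <- as.numeric(v)
    } else if (startsWith(k, "cq_loq.")) {
      loq[[substring(k, 8L)]] <- as.numeric(v)
    } else if (grepl("^gene\\.[^.]+\\.(role|file|standard)$", k)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
      id <- parts[2L]; field <- parts[3L]
      if (is.null(genes[[id]])) genes[[id]] <- list()
      genes[[id]][[field]] <- v
    } else {
      stop("unknown config key: '", k, "'")
    }
  }
  global_loq <- qc_args$cq_loq_global
  qc_args$cq_loq_global <- NULL
  if (length(loq)) {
    qc_args$cq_loq <- loq
  } else if (!is.null(global_loq)) {
    qc_args$cq_loq <- global_loq
  }
  qc <- do.call(qc_settings, qc_args)

  gene_df <- if (length(genes)) {
    do.call(rbind, lapply(names(genes), function(id) {
      g <- genes[[id]]
      if (is.null(g$role) || is.null(g$file))
        stop("gene '", id, "' needs both gene.", id, ".role and gene.",
             id, ".file")
      data.frame(gene_id = id, role = g$role, file = g$file,
                 standard = if (is.null(g$standard)) NA_character_
                            else g$standard,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene_id = character(), role = character(),
               file = character(), standard = character(),
               stringsAsFactors = FALSE)
  }
  list(qc = qc, genes = gene_df)
}

#' Load an experiment as declared by a run configuration
#'
#' Parses every gene table and standard table listed in the configuration
#' (paths resolved relative to the configuration file) and assembles the
#' experiment.
#'
#' @param path Path to the configuration file.
#' @param name Experiment name.
#' @return List with \code{experiment}, \code{standards} (named list of
#'   standard tables) and \code{qc}.
#' @export
load_run <- function(path, name = basename(path)) {
  cfg <- read_run_config(path)
  if (nrow(cfg$genes) == 0L) stop("config declares no gene tables")
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  ref_order <- 0L
  assays <- list(); standards <- list()
  for (i in seq_len(nrow(cfg$genes))) {
    g <- cfg$genes[i, ]
    io <- NA_integer_
    if (g$role == "reference") { ref_order <- ref_order + 1L; io <- ref_order }
    assays[[g$gene_id]] <- parse_gene_table(resolve(g$file), g$gene_id,
                                            g$role, import_order = io)
    if (!is.na(g$standard))
      standards[[g$gene_id]] <- parse_standard_table(resolve(g$standard))
  }
  list(experiment = experiment(assays, name = name),
       standards = standards, qc = cfg$qc)
}
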