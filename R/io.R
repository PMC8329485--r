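#' Read a centroided peak list from a delimited text file
#'
#' Accepts two-column TSV or CSV (m/z, intensity) with an optional header row.
#' The result is sorted ascending by m/z; peaks closer than 0.1 ppm are
#' collapsed to the most intense one. A message reports rows read versus kept,
#' and whether the input had to be re-sorted.
#'
#' @param path Path to the file.
#' @param polarity Ionization mode of the acquisition.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, polarity = "negative", sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty peak list file: ", path)
  sep <- if (grepl(",", lines[[1]])) "," else "\t| +"
  fields <- strsplit(lines, sep)
  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- all(is.na(first))   # a header row is non-numeric throughout
  start <- if (has_header) 2L else 1L
  if (has_header && length(lines) < 2) stop("no data rows in ", path)
  mz <- numeric(); inten <- numeric()
  for (i in start:length(lines)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (length(v) < 2 || anyNA(v[1:2])) {
      stop("parse error in ", path, " at line ", i - start + 1,
           ": '", lines[[i]], "'")
    }
    mz <- c(mz, v[1]); inten <- c(inten, v[2])
  }
  n_read <- length(mz)
  o <- order(mz)
  if (is.unsorted(mz)) message("read_peaklist: input not sorted by m/z; sorting")
  mz <- mz[o]; inten <- inten[o]
  # collapse duplicates within 0.1 ppm, keep the most intense
  keep <- rep(TRUE, length(mz))
  if (length(mz) > 1) {
    for (i in 2:length(mz)) {
      if ((mz[i] - mz[i - 1]) / mz[i] * 1e6 < 0.1) {
        drop_i <- if (inten[i] >= inten[i - 1]) i - 1 else i
        keep[drop_i] <- FALSE
      }
    }
  }
  mz <- mz[keep]; inten <- inten[keep]
  if (length(mz) < n_read) {
    message("read_peaklist: ", n_read, " rows read, ", length(mz),
            " kept after 0.1 ppm deduplication")
  }
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  peaklist(mz, inten, sample_id = sample_id, polarity = polarity)
}

#' Write a peak list as TSV
#'
#' @param x A [peaklist()].
#' @param path Output path; columns `mz`, `intensity` with header.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  utils::write.table(
    data.frame(mz = sprintf("%.8f", x$peaks$mz), intensity = x$peaks$intensity),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with columns `sample_id`, `starch_class`, and optionally
#' `injection_order` and `is_qc`. QC samples may have an empty class.
#'
#' @param path Path to the CSV.
#' @return Data frame with typed columns; sample ids checked unique.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "starch_class") %in% names(md))) {
    stop("metadata must have columns sample_id and starch_class")
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (is.null(md$is_qc)) md$is_qc <- FALSE
  md$is_qc <- as.logical(md$is_qc)
  if (any(!md$is_qc & (is.na(md$starch_class) | md$starch_class == ""))) {
    stop("every non-QC sample needs a starch_class")
  }
  md
}

#' Read MS2 spectra from an MGF file
#'
#' Parses standard Mascot Generic Format: `BEGIN IONS` / `END IONS` blocks
#' with a `PEPMASS` line, optional `TITLE` (used as feature id, else the block
#' index), and fragment `m/z intensity` rows.
#'
#' @param path Path to the MGF file.
#' @return List of [ms2spectrum()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  spectra <- list()
  in_block <- FALSE
  title <- NULL; pepmass <- NULL; fmz <- NULL; fint <- NULL
  block_i <- 0L
  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS")
      in_block <- TRUE; block_i <- block_i + 1L
      title <- NULL; pepmass <- NULL; fmz <- numeric(); fint <- numeric()
    } else if (ln == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS")
      if (is.null(pepmass)) stop("block ", block_i, " missing PEPMASS")
      id <- if (is.null(title)) as.character(block_i) else title
      spectra[[length(spectra) + 1L]] <-
        ms2spectrum(id, pepmass, fmz, fint)
      in_block <- FALSE
    } else if (in_block) {
      if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^PEPMASS=", ln)) {
        pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), " ")[[1]][1])
      } else if (grepl("^[A-Z]+=", ln)) {
        # other headers (CHARGE, RTINSECONDS, ...) ignored
      } else {
        v <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
        if (length(v) < 2 || anyNA(v[1:2])) stop("bad fragment line: '", ln, "'")
        fmz <- c(fmz, v[1]); fint <- c(fint, v[2])
      }
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block at end of file")
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate feature_id (TITLE) in MGF: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra List of [ms2spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$feature_id),
                 paste0("PEPMASS=", sprintf("%.6f", s$precursor_mz)),
                 sprintf("%.6f %.4f", s$fragments$mz, s$fragments$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Export a network to GraphML or edge TSV
#'
#' GraphML round-trips node ids, edge set, and string attributes through
#' igraph. The edge-TSV dialect is three columns: source, target, edge_label
#' (the reaction name or similarity, whichever edge attribute exists).
#'
#' @param graph An igraph object (as returned by [build_mdin()] or
#'   [build_similarity_network()]).
#' @param path Output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edge_tsv")) {
  stopifnot(igraph::is_igraph(graph))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    lab <- rep("", nrow(el))
    for (attr in c("reaction", "similarity")) {
      if (attr %in% igraph::edge_attr_names(graph)) {
        lab <- as.character(igraph::edge_attr(graph, attr))
        break
      }
    }
    df <- data.frame(source = el[, 1], target = el[, 2], edge_label = lab)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_graph_file()]
#'
#' @param path Input path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return An igraph object.
#' @export
read_graph_file <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
    if (nrow(df)) igraph::E(g)$edge_label <- df$edge_label
    g
  }
}
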