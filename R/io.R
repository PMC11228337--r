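#' Read a GEBV table
#'
#' Reads a delimited text table of GEBVs: one header row, first column
#' individual id, remaining columns numeric trait values. The delimiter
#' is auto-detected (tab or comma) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` (default) auto-detects `"\t"` vs
#'   `","` from the header line.
#' @return Numeric matrix with individual row names and trait column
#'   names.
#' @export
read_gebv <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("GEBV table needs an id column and at least one ",
                         "trait column", call. = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated individual id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  vals <- df[-1]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad)) {
      stop("non-numeric value '", vals[[j]][bad[1]], "' in column '",
           names(vals)[j], "', row ", bad[1], " of ", path, call. = FALSE)
    }
    if (anyNA(col)) {
      stop("missing value in column '", names(vals)[j], "', row ",
           which(is.na(col))[1], " of ", path, call. = FALSE)
    }
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a GEBV table
#'
#' Serialises a GEBV matrix as delimited text (17 significant digits, so
#' a write-read round trip reproduces the values to full double
#' precision).
#'
#' @param gebv numeric matrix with individual row names.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @param id_col name of the id column (default `"ID"`).
#' @return `path`, invisibly.
#' @export
write_gebv <- function(gebv, path, sep = "\t", id_col = "ID") {
  gebv <- as.matrix(gebv)
  ids <- rownames(gebv) %||% as.character(seq_len(nrow(gebv)))
  out <- data.frame(ids, apply(gebv, 2, sprintf, fmt = "%.17g"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(id_col, colnames(gebv))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square trait matrix
#'
#' Reads a square matrix (e.g. `G` or `P`) from delimited text with a
#' header row and a first column of trait labels, checks symmetry, and
#' reorders rows and columns to a requested trait order.
#'
#' @param path file path.
#' @param traits expected trait labels; the matrix is reordered to this
#'   order. `NULL` keeps the file order.
#' @param sep field delimiter; auto-detected when `NULL`.
#' @param tol asymmetry tolerance (default 1e-8).
#' @return n-by-n numeric matrix with trait dimnames.
#' @export
read_trait_matrix <- function(path, traits = NULL, sep = NULL, tol = 1e-8) {
  sep <- sep %||% detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labs <- as.character(df[[1]])
  M <- as.matrix(df[-1])
  rownames(M) <- labs
  if (nrow(M) != ncol(M)) {
    stop("matrix in ", path, " is not square (", nrow(M), " rows, ",
         ncol(M), " columns)", call. = FALSE)
  }
  if (!setequal(labs, colnames(M))) {
    stop("row and column labels differ in ", path, call. = FALSE)
  }
  M <- M[, labs, drop = FALSE]          # align columns with row order
  if (!is.null(traits)) {
    missing <- setdiff(traits, labs)
    extra <- setdiff(labs, traits)
    if (length(missing) || length(extra)) {
      stop("trait labels in ", path, " do not match; expected {",
           paste(traits, collapse = ", "), "}, found {",
           paste(labs, collapse = ", "), "}", call. = FALSE)
    }
    M <- M[traits, traits, drop = FALSE]
  }
  asym <- max(abs(M - t(M)))
  if (asym > tol) {
    stop("matrix in ", path, " is asymmetric (max |M - t(M)| = ",
         format(asym), ")", call. = FALSE)
  }
  M
}

#' Write a labelled square trait matrix
#'
#' @param M square numeric matrix with trait dimnames.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(M, path, sep = "\t") {
  M <- as.matrix(M)
  labs <- rownames(M) %||% paste0("trait", seq_len(nrow(M)))
  out <- data.frame(Trait = labs, apply(M, 2, sprintf, fmt = "%.17g"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("Trait", colnames(M) %||% labs)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-trait index report
#'
#' Serialises the [summary.dgi()] table (Trait, Sampled_d, Index_b,
#' Target_dg, Response_NoIteration, Response_Ref and, with candidates,
#' Response_Cand) as delimited text at full precision, plus an optional
#' human-readable variant rounded to 2 decimals.
#'
#' @param fit a fitted `"dgi"` object.
#' @param path output path for the full-precision report.
#' @param candidates optional candidate GEBV matrix.
#' @param rounded_path optional path for a 2-decimal variant.
#' @param sep field delimiter (default tab).
#' @return The report data frame, invisibly.
#' @export
write_report <- function(fit, path, candidates = NULL,
                         rounded_path = NULL, sep = "\t") {
  tab <- summary(fit, candidates = candidates)$table
  full <- tab
  full[-1] <- lapply(full[-1], sprintf, fmt = "%.17g")
  write.table(full, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(rounded_path)) {
    rtab <- tab
    rtab[-1] <- lapply(rtab[-1], round, digits = 2)
    write.table(rtab, rounded_path, sep = sep, quote = FALSE,
                row.names = FALSE)
  }
  invisible(tab)
}

#' Write the penalty trajectory log
#'
#' One row per iteration: the iteration number, the proposed penalty
#' `theta`, and whether the proposal was accepted (iteration 0 is the
#' starting state at `d = target`).
#'
#' @inheritParams write_report
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path, sep = "\t") {
  tr <- fit$trajectory
  tr$theta <- sprintf("%.17g", tr$theta)
  write.table(tr, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a
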