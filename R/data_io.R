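#' Micronucleus count datasets
#'
#' An `mn_dataset` holds one row per blood sample: identifiers, the known
#' neutron and photon doses (Gy; `NA` allowed only for prediction-only
#' samples), the per-sample histogram of micronuclei (MN) per binucleated
#' cell, and the number of scored cells. Histograms are stored canonically as
#' integer vectors of cell counts for MN values `0..K`, where `K` is the
#' largest MN count observed in that sample.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param neutron_dose,photon_dose numeric doses in Gy, `>= 0` or `NA`.
#' @param histograms list of histograms, one per sample. Each is either a
#'   named vector (names = MN count `k`) or an unnamed vector of counts for
#'   `k = 0, 1, ...`.
#' @param provenance free-text description of where the data came from.
#' @param allow_missing_dose if `FALSE` (default), `NA` doses are an error.
#'
#' @return A data frame of class `mn_dataset` with columns `sample_id`,
#'   `neutron_dose`, `photon_dose`, `n_cells` and the list column `histogram`.
#' @export
mn_dataset <- function(sample_id, neutron_dose, photon_dose, histograms,
                       provenance = "constructed in R",
                       allow_missing_dose = FALSE) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  stopifnot(length(neutron_dose) == length(sample_id),
            length(photon_dose) == length(sample_id),
            length(histograms) == length(sample_id))
  check_dose <- function(d, what) {
    bad <- !is.na(d) & d < 0
    if (any(bad)) {
      stop("negative ", what, " for sample ",
           paste(sample_id[bad], collapse = ", "))
    }
    if (!allow_missing_dose && anyNA(d)) {
      stop("missing ", what, " for sample ",
           paste(sample_id[is.na(d)], collapse = ", "),
           " (set allow_missing_dose = TRUE for prediction-only data)")
    }
  }
  check_dose(neutron_dose, "neutron_dose")
  check_dose(photon_dose, "photon_dose")
  histograms <- lapply(seq_along(histograms), function(i) {
    h <- tryCatch(canonical_histogram(histograms[[i]]),
                  error = function(e) {
                    stop("sample ", sample_id[i], ": ", conditionMessage(e),
                         call. = FALSE)
                  })
    h
  })
  out <- data.frame(sample_id = sample_id,
                    neutron_dose = as.numeric(neutron_dose),
                    photon_dose = as.numeric(photon_dose),
                    n_cells = vapply(histograms, sum, numeric(1)),
                    stringsAsFactors = FALSE)
  out$histogram <- histograms
  attr(out, "provenance") <- provenance
  class(out) <- c("mn_dataset", class(out))
  out
}

#' @export
print.mn_dataset <- function(x, ...) {
  cat(sprintf("mn_dataset: %d samples, %s cells total\n",
              nrow(x), format(sum(x$n_cells), big.mark = ",")))
  cat("provenance:", attr(x, "provenance") %||% "unknown", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonicalize an MN histogram
#'
#' Accepts a named (names = MN count) or unnamed (counts for k = 0,1,...)
#' vector and returns the canonical form: integer counts for k = 0..K with K
#' the largest observed MN count, names "0".."K". At least one cell required.
#'
#' @param h histogram vector.
#' @return named integer vector of cell counts.
#' @export
canonical_histogram <- function(h) {
  if (length(h) == 0) stop("empty histogram")
  v <- as.numeric(h)
  if (anyNA(v)) stop("histogram contains NA counts")
  if (any(v < 0)) stop("negative cell count in histogram")
  if (any(v != round(v))) stop("non-integer cell count in histogram")
  if (is.null(names(h))) {
    k <- seq_along(v) - 1L
  } else {
    k <- suppressWarnings(as.numeric(names(h)))
    if (anyNA(k) || any(k < 0) || any(k != round(k))) {
      stop("histogram names must be non-negative integer MN counts")
    }
  }
  if (sum(v) < 1) stop("histogram has no cells")
  kmax <- max(k[v > 0])
  out <- integer(kmax + 1L)
  for (i in seq_along(k)) {
    if (k[i] <= kmax) out[k[i] + 1L] <- out[k[i] + 1L] + as.integer(v[i])
  }
  names(out) <- as.character(0:kmax)
  out
}

#' Expand a histogram to one MN count per cell
#'
#' @param h histogram (any form accepted by [canonical_histogram()]).
#' @return integer vector with one element per scored cell.
#' @export
histogram_to_cells <- function(h) {
  h <- canonical_histogram(h)
  rep(as.integer(names(h)), h)
}

required_cols <- function(dialect) {
  base <- c("sample_id", "neutron_dose", "photon_dose")
  if (dialect == "long") c(base, "mn_count") else base
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (canon in names(col_map)) {
    actual <- col_map[[canon]]
    if (!actual %in% names(df)) {
      stop("column mapping refers to missing column '", actual, "'")
    }
    names(df)[names(df) == actual] <- canon
  }
  df
}

#' Read an MN count dataset from CSV
#'
#' Two dialects are supported. *Long*: one scored cell per row, columns
#' `sample_id, neutron_dose, photon_dose, mn_count`. *Wide*: one sample per
#' row, columns `sample_id, neutron_dose, photon_dose, n0, n1, ..., nK`
#' giving the number of cells with exactly 0..K micronuclei. `dialect =
#' "auto"` detects the dialect from the header (`mn_count` column implies
#' long). A column-mapping (`col_map = c(sample_id = "ID", ...)`) adapts
#' externally produced files without code changes.
#'
#' @param path CSV file (RFC-4180, UTF-8, header row).
#' @param dialect `"auto"`, `"long"` or `"wide"`.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's column names.
#' @param allow_missing_dose allow `NA` doses (prediction-only data).
#' @return an [mn_dataset()].
#' @export
read_mn_dataset <- function(path, dialect = c("auto", "long", "wide"),
                            col_map = NULL, allow_missing_dose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- apply_col_map(df, col_map)
  if (dialect == "auto") {
    dialect <- if ("mn_count" %in% names(df)) "long" else "wide"
  }
  missing <- setdiff(required_cols(dialect), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  prov <- sprintf("read from %s (%s dialect)", path, dialect)
  if (nrow(df) == 0) {
    out <- mn_dataset(character(), numeric(), numeric(), list(),
                      provenance = prov)
    return(out)
  }
  if (dialect == "long") {
    if (any(is.na(df$mn_count)) || any(df$mn_count < 0) ||
        any(df$mn_count != round(df$mn_count))) {
      bad <- unique(df$sample_id[is.na(df$mn_count) | df$mn_count < 0 |
                                   df$mn_count != round(df$mn_count)])
      stop("invalid mn_count for sample ", paste(bad, collapse = ", "))
    }
    ids <- unique(df$sample_id)
    per <- lapply(ids, function(id) df[df$sample_id == id, , drop = FALSE])
    for (p in per) {
      if (length(unique(p$neutron_dose)) > 1 ||
          length(unique(p$photon_dose)) > 1) {
        stop("inconsistent doses within sample ", p$sample_id[1])
      }
    }
    hist <- lapply(per, function(p) table_to_histogram(p$mn_count))
    mn_dataset(ids,
               vapply(per, function(p) p$neutron_dose[1], numeric(1)),
               vapply(per, function(p) p$photon_dose[1], numeric(1)),
               hist, provenance = prov,
               allow_missing_dose = allow_missing_dose)
  } else {
    count_cols <- grep("^n[0-9]+$", names(df), value = TRUE)
    if (!length(count_cols)) {
      stop("missing required column(s): n0, n1, ... (wide count columns)")
    }
    ks <- as.integer(sub("^n", "", count_cols))
    count_cols <- count_cols[order(ks)]
    hist <- lapply(seq_len(nrow(df)), function(i) {
      v <- as.numeric(unlist(df[i, count_cols]))
      names(v) <- sort(ks)
      v
    })
    mn_dataset(df$sample_id, df$neutron_dose, df$photon_dose, hist,
               provenance = prov, allow_missing_dose = allow_missing_dose)
  }
}

table_to_histogram <- function(counts) {
  tb <- table(factor(counts, levels = 0:max(counts)))
  v <- as.integer(tb)
  names(v) <- names(tb)
  v
}

#' Write an MN count dataset to CSV
#'
#' Round-trip safe: `read_mn_dataset(write_mn_dataset(d, p), dialect)`
#' reproduces `d`'s histograms, ids and doses exactly (doses to full double
#' precision). Wide output extends count columns to the maximum MN count
#' observed anywhere in the dataset.
#'
#' @param dataset an [mn_dataset()].
#' @param path output file path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_mn_dataset <- function(dataset, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    kmax <- if (nrow(dataset)) {
      max(vapply(dataset$histogram, function(h) length(h) - 1L, integer(1)))
    } else 0L
    counts <- t(vapply(dataset$histogram, function(h) {
      c(h, integer(kmax + 1L - length(h)))
    }, numeric(kmax + 1L)))
    if (nrow(dataset) == 0) counts <- matrix(numeric(0), 0, kmax + 1L)
    colnames(counts) <- paste0("n", 0:kmax)
    out <- cbind(dataset[, c("sample_id", "neutron_dose", "photon_dose")],
                 as.data.frame(counts))
  } else {
    rows <- lapply(seq_len(nrow(dataset)), function(i) {
      cells <- histogram_to_cells(dataset$histogram[[i]])
      data.frame(sample_id = dataset$sample_id[i],
                 neutron_dose = dataset$neutron_dose[i],
                 photon_dose = dataset$photon_dose[i],
                 mn_count = cells, stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), neutron_dose = numeric(),
                 photon_dose = numeric(), mn_count = integer())
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Keep samples with at least `min_cells` scored cells
#'
#' The analyses of large-sample subsets use a 300-cell cutoff, consistent
#' with IAEA/ISO sample-size recommendations; the threshold is inclusive.
#' Order is preserved and the operation is idempotent and monotone in
#' `min_cells`.
#'
#' @param dataset an [mn_dataset()].
#' @param min_cells positive integer threshold.
#' @return filtered [mn_dataset()].
#' @export
filter_min_cells <- function(dataset, min_cells) {
  stopifnot(min_cells >= 1)
  keep <- dataset$n_cells >= min_cells
  out <- dataset[keep, , drop = FALSE]
  attr(out, "provenance") <- sprintf("%s; filtered to >= %d cells",
                                     attr(dataset, "provenance") %||% "?",
                                     min_cells)
  class(out) <- class(dataset)
  out
}
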