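# Data model and I/O for 384-well viability screen plates.

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
WELL_ROLES <- c("library", "neg_control", "pos_control", "untreated", "empty")
CELL_CLASSES <- c("MSC", "fibroblast_primary", "fibroblast_line")

#' Well address helpers
#'
#' 384-well addresses use the letter-row convention: rows `A`-`P`, columns
#' `1`-`24`, printed as the row letter followed by the zero-padded column
#' (`"G04"`). `well_name()` builds address strings, `parse_well()` splits
#' them back into row letters and column numbers, and `all_wells()`
#' enumerates the full plate in row-major order (`A01` ... `A24`, `B01`,
#' ...).
#'
#' @param row Character vector of row letters (`"A"`-`"P"`).
#' @param column Integer vector of columns (1-24).
#' @param well Character vector of well addresses such as `"G04"`.
#' @return `well_name()` and `all_wells()` return character vectors;
#'   `parse_well()` returns a data frame with columns `row` and `column`.
#' @examples
#' well_name("G", 4)
#' parse_well("P24")
#' length(all_wells())
#' @export
well_name <- function(row, column) {
  if (!all(row %in% PLATE_ROWS)) {
    stop("well row must be one of A-P", call. = FALSE)
  }
  if (!all(column %in% PLATE_COLS)) {
    stop("well column must be within 1-24", call. = FALSE)
  }
  sprintf("%s%02d", row, as.integer(column))
}

#' @rdname well_name
#' @export
parse_well <- function(well) {
  ok <- grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", well)
  if (!all(ok)) {
    stop("malformed well address: ", paste(unique(well[!ok]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(row = substr(well, 1, 1),
             column = as.integer(substr(well, 2, 3)),
             stringsAsFactors = FALSE)
}

#' @rdname well_name
#' @export
all_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, well_name)))
}

#' Default arrayed kinome plate layout
#'
#' Builds the plate set for an arrayed siRNA library in 384-well plates:
#' library reagents fill columns 5-24 row-major (`A05`..`A24`, then `B05`,
#' ...; 320 wells per full plate), negative controls (Rluc) sit at
#' `G04`-`J04`, positive controls (UBC) at `F03`-`I03`, untreated wells
#' default to `K03`-`N03`, and every other well in columns 1-4 is empty.
#' The last plate is partially filled when the library size is not a
#' multiple of 320; a 778-gene kinome spreads over 3 plates with 320, 320
#' and 138 library wells.
#'
#' @param gene_ids Character vector of distinct library gene identifiers,
#'   one per library well, placed in order.
#' @param untreated_wells Well addresses carrying untreated (no-reagent)
#'   cells on every plate. The positions are a package default, not an
#'   assay constant, and can be moved anywhere in the control columns 1-4.
#' @param plate_prefix Prefix for generated plate identifiers
#'   (`"plate1"`, `"plate2"`, ...).
#' @return A data frame (one row per well across all plates) with columns
#'   `plate_id`, `well`, `role` (`library`, `neg_control`, `pos_control`,
#'   `untreated`, `empty`) and `target` (gene id for library wells,
#'   `"Rluc"`/`"UBC"`/`"NT"` for controls, `""` for empty wells).
#' @examples
#' layout <- default_kinome_layout(sprintf("KIN%03d", 1:778))
#' table(layout$role)
#' @export
default_kinome_layout <- function(gene_ids,
                                  untreated_wells = c("K03", "L03", "M03", "N03"),
                                  plate_prefix = "plate") {
  if (length(gene_ids) < 1L) {
    stop("gene_ids must contain at least one gene", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be distinct", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  neg_wells <- well_name(c("G", "H", "I", "J"), 4)
  pos_wells <- well_name(c("F", "G", "H", "I"), 3)
  untreated_wells <- as.character(untreated_wells)
  parsed_nt <- parse_well(untreated_wells)
  reserved <- c(neg_wells, pos_wells)
  if (any(untreated_wells %in% reserved)) {
    stop("untreated wells collide with fixed control positions", call. = FALSE)
  }
  if (any(parsed_nt$column > 4)) {
    stop("untreated wells must lie in the control columns 1-4", call. = FALSE)
  }

  # row-major library block: A05..A24, B05..B24, ..., P05..P24
  lib_wells <- as.vector(t(outer(PLATE_ROWS, 5:24, well_name)))
  per_plate <- length(lib_wells)
  n_plates <- ceiling(length(gene_ids) / per_plate)

  plates <- lapply(seq_len(n_plates), function(p) {
    plate_id <- paste0(plate_prefix, p)
    wells <- all_wells()
    role <- rep("empty", length(wells))
    target <- rep("", length(wells))
    genes_p <- gene_ids[((p - 1L) * per_plate + 1L):min(p * per_plate, length(gene_ids))]
    filled <- lib_wells[seq_along(genes_p)]
    role[match(filled, wells)] <- "library"
    target[match(filled, wells)] <- genes_p
    role[match(neg_wells, wells)] <- "neg_control"
    target[match(neg_wells, wells)] <- "Rluc"
    role[match(pos_wells, wells)] <- "pos_control"
    target[match(pos_wells, wells)] <- "UBC"
    role[match(untreated_wells, wells)] <- "untreated"
    target[match(untreated_wells, wells)] <- "NT"
    data.frame(plate_id = plate_id, well = wells, role = role,
               target = target, stringsAsFactors = FALSE)
  })
  do.call(rbind, plates)
}

validate_layout <- function(layout) {
  need <- c("plate_id", "well", "role", "target")
  if (!all(need %in% names(layout))) {
    stop("layout must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(layout$role), WELL_ROLES)
  if (length(bad_role)) {
    stop("unknown well role: ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  full <- all_wells()
  for (pid in unique(layout$plate_id)) {
    wells <- layout$well[layout$plate_id == pid]
    missing <- setdiff(full, wells)
    if (length(missing) || length(wells) != 384L) {
      stop("incomplete layout for plate ", pid,
           if (length(missing)) paste0(": missing ", paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    parse_well(wells)
    lib <- layout[layout$plate_id == pid & layout$role == "library", ]
    if (any(!nzchar(lib$target))) {
      stop("library wells without target on plate ", pid, call. = FALSE)
    }
    if (anyDuplicated(lib$target)) {
      stop("duplicated library target on plate ", pid, ": ",
           lib$target[duplicated(lib$target)][1], call. = FALSE)
    }
  }
  gene_all <- layout$target[layout$role == "library"]
  if (anyDuplicated(gene_all)) {
    stop("library target appears on more than one plate: ",
         gene_all[duplicated(gene_all)][1], call. = FALSE)
  }
  invisible(layout)
}

validate_samples <- function(samples) {
  need <- c("sample_id", "cell_class", "donor_id", "preparation_id")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(samples$cell_class), CELL_CLASSES)
  if (length(bad)) {
    stop("unknown cell_class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # a preparation belongs to exactly one donor
  map <- unique(samples[, c("preparation_id", "donor_id")])
  if (anyDuplicated(map$preparation_id)) {
    stop("preparation_id mapped to more than one donor", call. = FALSE)
  }
  invisible(samples)
}

#' Assemble and validate a screen dataset
#'
#' A screen dataset bundles the sample annotation (sample, cell class,
#' donor, preparation), the plate layouts, and the well-level luminescence
#' measurements of every replicate screen. Construction cross-validates
#' all invariants: complete 384-well layouts, known sample and plate
#' references, non-negative finite RLU, and full library coverage by each
#' (sample, replicate) screen. Violations are reported with plate/well
#' coordinates.
#'
#' @param samples Data frame with columns `sample_id`, `cell_class`
#'   (`MSC`, `fibroblast_primary`, `fibroblast_line`), `donor_id`,
#'   `preparation_id`.
#' @param layouts Data frame as returned by [default_kinome_layout()].
#' @param measurements Data frame with columns `plate_id`, `sample_id`,
#'   `replicate_id`, `well`, `rlu` (relative light units, `>= 0`).
#' @return An object of class `screen_dataset`: a list with elements
#'   `samples`, `layouts`, `measurements`.
#' @seealso [read_screen()], [simulate_screen()]
#' @export
screen_dataset <- function(samples, layouts, measurements) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  layouts <- as.data.frame(layouts, stringsAsFactors = FALSE)
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  validate_samples(samples)
  validate_layout(layouts)

  need <- c("plate_id", "sample_id", "replicate_id", "well", "rlu")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  measurements$rlu <- as.numeric(measurements$rlu)
  bad <- !is.finite(measurements$rlu) | measurements$rlu < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid RLU %s at plate %s well %s (sample %s, replicate %s)",
                 format(measurements$rlu[i]), measurements$plate_id[i],
                 measurements$well[i], measurements$sample_id[i],
                 measurements$replicate_id[i]), call. = FALSE)
  }
  unknown_sample <- setdiff(unique(measurements$sample_id), samples$sample_id)
  if (length(unknown_sample)) {
    stop("measurements reference unknown sample_id: ",
         paste(unknown_sample, collapse = ", "), call. = FALSE)
  }
  unknown_plate <- setdiff(unique(measurements$plate_id), unique(layouts$plate_id))
  if (length(unknown_plate)) {
    stop("measurements reference unknown plate_id: ",
         paste(unknown_plate, collapse = ", "), call. = FALSE)
  }

  # each measured plate instance must cover exactly the layout's wells,
  # and each (sample, replicate) screen must cover the full library
  full <- all_wells()
  key <- interaction(measurements$plate_id, measurements$sample_id,
                     measurements$replicate_id, drop = TRUE)
  for (k in levels(key)) {
    rows <- measurements[key == k, ]
    missing <- setdiff(full, rows$well)
    if (length(missing) || nrow(rows) != 384L) {
      stop("plate ", rows$plate_id[1], " of sample ", rows$sample_id[1],
           " replicate ", rows$replicate_id[1],
           " does not cover all 384 wells",
           if (length(missing)) paste0(" (missing ",
                                       paste(utils::head(missing, 5), collapse = ", "), ")"),
           call. = FALSE)
    }
  }
  plate_ids <- unique(layouts$plate_id)
  screens <- unique(measurements[, c("sample_id", "replicate_id")])
  for (i in seq_len(nrow(screens))) {
    have <- unique(measurements$plate_id[
      measurements$sample_id == screens$sample_id[i] &
        measurements$replicate_id == screens$replicate_id[i]])
    missing <- setdiff(plate_ids, have)
    if (length(missing)) {
      stop("screen ", screens$sample_id[i], " replicate ",
           screens$replicate_id[i], " misses plates: ",
           paste(missing, collapse = ", "),
           " and does not cover the full gene library", call. = FALSE)
    }
  }

  structure(list(samples = samples, layouts = layouts,
                 measurements = measurements),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  genes <- sum(x$layouts$role == "library")
  screens <- unique(x$measurements[, c("sample_id", "replicate_id")])
  cat("screen_dataset:", nrow(x$samples), "samples,",
      length(unique(x$layouts$plate_id)), "plates,",
      genes, "library genes,", nrow(screens), "replicate screens\n")
  invisible(x)
}

#' Gene identifiers of a screen dataset
#'
#' @param dataset A `screen_dataset`.
#' @return Character vector of library gene ids in plate/layout order.
#' @export
library_genes <- function(dataset) {
  dataset$layouts$target[dataset$layouts$role == "library"]
}

read_tsv_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop("file ", path, " misses columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[columns]
}

#' Read a screen dataset from TSV files
#'
#' Reads the three tab-separated files describing one screen (UTF-8,
#' header row, `.` decimal separator) and returns a fully cross-validated
#' [screen_dataset()]. Invariant violations (missing wells, unknown
#' samples, negative RLU, ...) abort with the offending plate/well named.
#'
#' @param measurement_path TSV with columns `plate_id`, `sample_id`,
#'   `replicate_id`, `well`, `rlu`.
#' @param layout_path TSV with columns `plate_id`, `well`, `role`,
#'   `target`.
#' @param samples_path TSV with columns `sample_id`, `cell_class`,
#'   `donor_id`, `preparation_id`.
#' @return A `screen_dataset`.
#' @seealso [write_screen()]
#' @export
read_screen <- function(measurement_path, layout_path, samples_path) {
  measurements <- read_tsv_checked(
    measurement_path, c("plate_id", "sample_id", "replicate_id", "well", "rlu"))
  suppressWarnings(rlu <- as.numeric(measurements$rlu))
  if (anyNA(rlu)) {
    i <- which(is.na(rlu))[1]
    stop("non-numeric RLU at plate ", measurements$plate_id[i], " well ",
         measurements$well[i], call. = FALSE)
  }
  measurements$rlu <- rlu
  layouts <- read_tsv_checked(layout_path, c("plate_id", "well", "role", "target"))
  samples <- read_tsv_checked(
    samples_path, c("sample_id", "cell_class", "donor_id", "preparation_id"))
  screen_dataset(samples, layouts, measurements)
}

write_tsv <- function(df, path, digits = 17) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a screen dataset to TSV files
#'
#' Writes `measurements.tsv`, `layout.tsv` and `samples.tsv` into `dir`
#' in the dialect that [read_screen()] consumes; reading the files back
#' reproduces the dataset (numeric values to 12+ significant digits).
#'
#' @param dataset A `screen_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_screen <- function(dataset, dir) {
  stopifnot(inherits(dataset, "screen_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.tsv"),
             layout = file.path(dir, "layout.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_tsv(dataset$measurements, paths["measurements"])
  write_tsv(dataset$layouts, paths["layout"])
  write_tsv(dataset$samples, paths["samples"])
  invisible(paths)
}

#' Write and read per-gene score tables
#'
#' `write_scores()` writes a [score_genes()] table as TSV with fixed
#' column order and deterministic row order (gene, then sample,
#' lexicographic); numeric values survive a round trip to at least 12
#' significant digits. `read_scores()` reads such a file back.
#'
#' @param table A gene score table (data frame) from [score_genes()].
#' @param path File path.
#' @return `write_scores()` returns the path invisibly; `read_scores()`
#'   returns the table.
#' @export
write_scores <- function(table, path) {
  if (is.null(table) || nrow(table) == 0L) {
    stop("score table is empty", call. = FALSE)
  }
  cols <- c("gene", "sample_id", "plate_id", "rel_viability", "log2_ctrl",
            "log2_score", "zscore", "n_replicates")
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("score table misses columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  table <- table[order(table$gene, table$sample_id), cols]
  write_tsv(table, path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read_tsv_checked(path, c("gene", "sample_id", "plate_id",
                                 "rel_viability", "log2_ctrl", "log2_score",
                                 "zscore", "n_replicates"))
  for (col in c("rel_viability", "log2_ctrl", "log2_score", "zscore")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$n_replicates <- as.integer(df$n_replicates)
  df
}
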