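#' @importFrom utils read.table write.table
NULL

# Founder marker used in PED-dialect files for a missing parent.
PED_FOUNDER <- "0"

.SEX_LEVELS <- c("male", "female", "unknown")
.AFF_LEVELS <- c("affected", "unaffected", "unknown")

#' Construct a validated pedigree
#'
#' A pedigree is a data frame with one row per individual and the columns
#' `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`
#' (`"male"`/`"female"`/`"unknown"`), `affected`
#' (`"affected"`/`"unaffected"`/`"unknown"`), `z_ls` and `z_fn` (DXA
#' bone-mineral-density Z-scores at lumbar spine and femoral neck, in SD
#' units, `NA` if not measured). A missing parent is encoded with the
#' founder marker `"0"`. The affection label is an input: it is never
#' derived from, or overwritten by, the Z-score classification helpers.
#'
#' @param individuals data frame with the columns above.
#' @param proband_id id of the index individual; must resolve to a row
#'   labelled `affected`.
#' @return An object of class `hbm_pedigree` (a data frame with a
#'   `proband_id` attribute).
#' @seealso [read_pedigree()], [classify_bmd()], [study_pedigree()]
#' @export
pedigree <- function(individuals, proband_id) {
  req <- c("family_id", "individual_id", "father_id", "mother_id",
           "sex", "affected", "z_ls", "z_fn")
  missing_cols <- setdiff(req, names(individuals))
  if (length(missing_cols) > 0L) {
    stop("pedigree is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ind <- as.data.frame(individuals)[, req]
  ind$family_id <- as.character(ind$family_id)
  ind$individual_id <- as.character(ind$individual_id)
  ind$father_id <- as.character(ind$father_id)
  ind$mother_id <- as.character(ind$mother_id)
  ind$sex <- as.character(ind$sex)
  ind$affected <- as.character(ind$affected)
  ind$z_ls <- as.numeric(ind$z_ls)
  ind$z_fn <- as.numeric(ind$z_fn)

  if (any(!ind$sex %in% .SEX_LEVELS)) {
    stop("invalid sex value(s): ",
         paste(unique(ind$sex[!ind$sex %in% .SEX_LEVELS]), collapse = ", "))
  }
  if (any(!ind$affected %in% .AFF_LEVELS)) {
    stop("invalid affection value(s): ",
         paste(unique(ind$affected[!ind$affected %in% .AFF_LEVELS]), collapse = ", "))
  }
  dup <- ind$individual_id[duplicated(paste(ind$family_id, ind$individual_id))]
  if (length(dup) > 0L) {
    stop("duplicate individual_id within family: ", paste(unique(dup), collapse = ", "))
  }
  for (col in c("father_id", "mother_id")) {
    ref <- ind[[col]]
    dangling <- setdiff(ref[ref != PED_FOUNDER], ind$individual_id)
    if (length(dangling) > 0L) {
      stop(col, " references unknown individual(s): ",
           paste(dangling, collapse = ", "))
    }
  }
  .check_acyclic(ind)

  proband_id <- as.character(proband_id)
  if (length(proband_id) != 1L || !proband_id %in% ind$individual_id) {
    stop("proband_id '", proband_id, "' not found in pedigree")
  }
  if (ind$affected[ind$individual_id == proband_id] != "affected") {
    stop("proband '", proband_id, "' is not labelled affected")
  }

  rownames(ind) <- NULL
  structure(ind, proband_id = proband_id,
            class = c("hbm_pedigree", "data.frame"))
}

# Parent graph must be acyclic: peel individuals whose parents are all
# founders or already peeled; anything left over sits on a cycle.
.check_acyclic <- function(ind) {
  resolved <- character(0)
  remaining <- ind$individual_id
  repeat {
    ready <- vapply(remaining, function(id) {
      row <- ind[ind$individual_id == id, ]
      all(c(row$father_id, row$mother_id) %in% c(PED_FOUNDER, resolved))
    }, logical(1))
    if (!any(ready)) break
    resolved <- c(resolved, remaining[ready])
    remaining <- remaining[!ready]
    if (length(remaining) == 0L) return(invisible(TRUE))
  }
  stop("pedigree parent graph contains a cycle involving: ",
       paste(remaining, collapse = ", "))
}

#' @export
print.hbm_pedigree <- function(x, ...) {
  cat(sprintf("hbm_pedigree: %d individuals (%d affected), proband %s\n",
              nrow(x), sum(x$affected == "affected"), attr(x, "proband_id")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname pedigree_accessors
#' @export
proband_id <- function(ped) attr(ped, "proband_id")

#' Pedigree accessors
#'
#' `affected_ids()` and `unaffected_ids()` return the individual ids carrying
#' the corresponding input affection label; individuals labelled `unknown`
#' belong to neither set and are ignored by the segregation machinery.
#'
#' @param ped an `hbm_pedigree`.
#' @return Character vector of individual ids (`proband_id()`: a single id).
#' @name pedigree_accessors
#' @export
affected_ids <- function(ped) ped$individual_id[ped$affected == "affected"]

#' @rdname pedigree_accessors
#' @export
unaffected_ids <- function(ped) ped$individual_id[ped$affected == "unaffected"]

# Individual ids ordered so that every parent precedes its children.
.topological_order <- function(ped) {
  order <- character(0)
  remaining <- ped$individual_id
  while (length(remaining) > 0L) {
    ready <- vapply(remaining, function(id) {
      row <- ped[ped$individual_id == id, ]
      all(c(row$father_id, row$mother_id) %in% c(PED_FOUNDER, order))
    }, logical(1))
    order <- c(order, remaining[ready])
    remaining <- remaining[!ready]
  }
  order
}

#' Read an extended PED file
#'
#' Parses the tab-separated extended-PED dialect: columns `family_id`,
#' `individual_id`, `father_id`, `mother_id`, `sex` (1 = male, 2 = female,
#' 0 = unknown), `affected` (2 = affected, 1 = unaffected, 0 = unknown),
#' `z_ls`, `z_fn` (`.` for a missing Z-score). Lines starting with `#` are
#' comments; an optional header line is introduced the same way.
#'
#' @param path path to the file.
#' @param proband_id id of the index individual.
#' @return A validated [pedigree()].
#' @export
read_pedigree <- function(path, proband_id) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 8L)
  if (length(bad) > 0L) {
    stop("malformed pedigree row at line ", which(keep)[bad[1]],
         ": expected 8 tab-separated fields, got ", lengths(rows)[bad[1]])
  }
  m <- do.call(rbind, rows)
  parse_z <- function(x) {
    x[x == "."] <- NA_character_
    suppressWarnings(z <- as.numeric(x))
    if (any(is.na(z) & !is.na(x))) {
      stop("non-numeric Z-score value(s): ",
           paste(x[is.na(z) & !is.na(x)], collapse = ", "))
    }
    z
  }
  decode <- function(x, map, what) {
    if (any(!x %in% names(map))) {
      stop("invalid ", what, " code(s): ",
           paste(unique(x[!x %in% names(map)]), collapse = ", "))
    }
    unname(map[x])
  }
  ind <- data.frame(
    family_id = m[, 1], individual_id = m[, 2],
    father_id = m[, 3], mother_id = m[, 4],
    sex = decode(m[, 5], c(`1` = "male", `2` = "female", `0` = "unknown"), "sex"),
    affected = decode(m[, 6], c(`2` = "affected", `1` = "unaffected", `0` = "unknown"),
                      "affection"),
    z_ls = parse_z(m[, 7]), z_fn = parse_z(m[, 8]),
    stringsAsFactors = FALSE
  )
  pedigree(ind, proband_id)
}

#' Write an extended PED file
#'
#' Inverse of [read_pedigree()]: `read_pedigree(write_pedigree(ped, f), pid)`
#' is the identity on validated pedigrees.
#'
#' @param ped an `hbm_pedigree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "hbm_pedigree"))
  enc <- function(x, map) unname(map[x])
  fmt_z <- function(z) ifelse(is.na(z), ".", format(z, trim = TRUE, digits = 10))
  body <- cbind(
    ped$family_id, ped$individual_id, ped$father_id, ped$mother_id,
    enc(ped$sex, c(male = "1", female = "2", unknown = "0")),
    enc(ped$affected, c(affected = "2", unaffected = "1", unknown = "0")),
    fmt_z(ped$z_ls), fmt_z(ped$z_fn)
  )
  header <- "#family_id\tindividual_id\tfather_id\tmother_id\tsex\taffected\tz_ls\tz_fn"
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}
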