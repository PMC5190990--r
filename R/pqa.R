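#' Build a point-quadrat insertion table
#'
#' One row per rod insertion: the vine, the wire-relative height level and
#' the ordered contact sequence, encoded as a `";"`-separated token string
#' (`"L"` = leaf, `"C"` = cluster; empty string = canopy gap).
#'
#' @param vine_id Character vector of vine identifiers.
#' @param level_cm Heights relative to the support wire, cm; must belong to
#'   the 18 standard levels ([pqa_levels()]).
#' @param contacts Character vector of contact sequences, e.g. `"L;L;C;L"`,
#'   `""` for a gap. Full words `LEAF`/`CLUSTER` are also accepted.
#' @return A data frame of class `pqa_insertions`.
#' @export
pqa_insertions <- function(vine_id, level_cm, contacts) {
  n <- length(contacts)
  if (length(vine_id) != n || length(level_cm) != n) {
    stop("vine_id, level_cm and contacts must have equal length", call. = FALSE)
  }
  if (!all(level_cm %in% pqa_levels())) {
    stop("level_cm must be one of the 18 point-quadrat levels (-15, -5, ..., 155)",
         call. = FALSE)
  }
  contacts <- toupper(trimws(as.character(contacts)))
  contacts[is.na(contacts)] <- ""
  lapply(strsplit(contacts, ";", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok)]
    bad <- !(tok %in% c("L", "C", "LEAF", "CLUSTER"))
    if (any(bad)) stop("unknown contact token: ", tok[bad][1L], call. = FALSE)
  })
  out <- data.frame(vine_id = as.character(vine_id),
                    level_cm = as.numeric(level_cm),
                    contacts = contacts, stringsAsFactors = FALSE)
  class(out) <- c("pqa_insertions", "data.frame")
  out
}

# Tokenize one contact string into "L"/"C" tokens.
contact_tokens <- function(s) {
  tok <- strsplit(toupper(s), ";", fixed = TRUE)[[1L]]
  tok <- tok[nzchar(tok)]
  ifelse(tok %in% c("LEAF", "L"), "L", "C")
}

# Per-insertion summary: leaf count, gap flag, interior-leaf count.
insertion_stats <- function(contacts) {
  m <- t(vapply(contacts, function(s) {
    tok <- contact_tokens(s)
    n_leaf <- sum(tok == "L")
    # interior leaf: at least one other leaf before AND after it in the same
    # insertion; clusters do not shield leaves
    n_int <- max(n_leaf - 2L, 0L)
    c(n_leaf, as.integer(length(tok) == 0L), n_int)
  }, numeric(3L), USE.NAMES = FALSE))
  colnames(m) <- c("n_leaf", "gap", "interior")
  m
}

#' Point-quadrat canopy metrics (Smart & Robinson scoring)
#'
#' From a set of rod insertions computes the three standard canopy-structure
#' metrics: leaf layer number `LLN` (mean leaf contacts per insertion),
#' percent canopy gaps `%CG` (insertions with no contact of any type), and
#' percent interior leaves `%IL` (leaf contacts that are neither the first
#' nor the last leaf of their insertion, as a percentage of all leaf
#' contacts; defined as 0, flagged, when there are no leaf contacts).
#'
#' @param insertions A [pqa_insertions()] table (or a data frame with
#'   columns `vine_id`, `level_cm`, `contacts`).
#' @param by Aggregation scope: `"overall"`, `"vine"`, `"level"` or
#'   `"vine_level"`.
#' @return A data frame with the scope columns plus `n_insertions`, `lln`,
#'   `cg_pct`, `il_pct` and `il_defined` (FALSE where `%IL` was flagged).
#' @examples
#' ins <- pqa_insertions(rep("v1", 4), rep(35, 4), c("L;L;L", "L", "", "L;C;L"))
#' pqa_metrics(ins)  # LLN 1.5, %CG 25, %IL 16.7
#' @export
pqa_metrics <- function(insertions,
                        by = c("overall", "vine", "level", "vine_level")) {
  by <- match.arg(by)
  req <- c("vine_id", "level_cm", "contacts")
  if (!all(req %in% names(insertions))) {
    stop("insertions need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(insertions) == 0L) stop("zero insertions", call. = FALSE)
  st <- insertion_stats(insertions$contacts)
  key <- switch(by,
    overall    = rep("all", nrow(insertions)),
    vine       = insertions$vine_id,
    level      = as.character(insertions$level_cm),
    vine_level = paste(insertions$vine_id, insertions$level_cm, sep = "@"))
  groups <- split(seq_len(nrow(insertions)), key)
  rows <- lapply(names(groups), function(k) {
    i <- groups[[k]]
    n <- length(i)
    leaves <- sum(st[i, "n_leaf"])
    il_defined <- leaves > 0
    data.frame(
      group = k, n_insertions = n,
      lln = leaves / n,
      cg_pct = 100 * sum(st[i, "gap"]) / n,
      il_pct = if (il_defined) 100 * sum(st[i, "interior"]) / leaves else 0,
      il_defined = il_defined,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (by == "vine") names(out)[1L] <- "vine_id"
  if (by == "level") {
    names(out)[1L] <- "level_cm"
    out$level_cm <- as.numeric(out$level_cm)
    out <- out[order(out$level_cm), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (by == "vine_level") {
    parts <- strsplit(out$group, "@", fixed = TRUE)
    out$vine_id <- vapply(parts, `[`, "", 1L)
    out$level_cm <- as.numeric(vapply(parts, `[`, "", 2L))
    out$group <- NULL
    out <- out[, c("vine_id", "level_cm", "n_insertions", "lln", "cg_pct",
                   "il_pct", "il_defined")]
  }
  out
}

#' Read / write a point-quadrat insertion table (CSV)
#'
#' CSV columns: `vine_id`, `level_cm`, `contacts` (empty string for a gap).
#'
#' @param path File path.
#' @param insertions A [pqa_insertions()] table.
#' @return `read_pqa_table()` returns a `pqa_insertions` table;
#'   `write_pqa_table()` returns `path` invisibly.
#' @export
read_pqa_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(contacts = "character"))
  pqa_insertions(df$vine_id, df$level_cm, df$contacts)
}

#' @rdname read_pqa_table
#' @export
write_pqa_table <- function(insertions, path) {
  utils::write.csv(as.data.frame(insertions), path, row.names = FALSE)
  invisible(path)
}

#' Canopy porosity from light-scanner readings
#'
#' `CP = 1 - M_a / Max`, where `M_a` is the mean of the below-canopy
#' irradiance readings and `Max` the mean of the above-canopy reference
#' readings. Values below 0 (below readings exceeding the reference, sensor
#' noise) are clamped to 0 with a warning.
#'
#' @param below Below-canopy readings (irradiance or raw mV; units must
#'   match `above`). Non-negative.
#' @param above Above-canopy reference readings; positive mean required.
#' @return Canopy porosity in `[0, 1]`.
#' @examples
#' canopy_porosity(below = c(150, 250), above = c(800, 800))  # 0.75
#' @export
canopy_porosity <- function(below, above) {
  if (length(below) == 0L || length(above) == 0L) {
    stop("empty reading sets", call. = FALSE)
  }
  if (anyNA(below) || anyNA(above)) stop("readings must not be NA", call. = FALSE)
  if (any(below < 0) || any(above < 0)) {
    stop("readings must be non-negative", call. = FALSE)
  }
  ma <- mean(below)
  mx <- mean(above)
  if (mx <= 0) stop("above-canopy reference mean must be positive",
                    call. = FALSE)
  cp <- 1 - ma / mx
  if (cp < 0) {
    warning("below-canopy mean exceeds the reference; porosity clamped to 0")
    cp <- 0
  }
  cp
}

#' Read a light-scanner CSV
#'
#' Expects columns `reading_type` (`"below"` or `"above"`) and `value`.
#'
#' @param path CSV path.
#' @return List with numeric vectors `below` and `above`.
#' @export
read_light_scan <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("reading_type", "value") %in% names(df))) {
    stop("light scan CSV needs columns reading_type, value", call. = FALSE)
  }
  list(below = df$value[df$reading_type == "below"],
       above = df$value[df$reading_type == "above"])
}
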