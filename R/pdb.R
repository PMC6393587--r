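#' Multi-model PDB input and output
#'
#' Minimal fixed-column PDB reader/writer for conformer ensembles: each
#' MODEL/ENDMDL block is one conformer, water molecules are HETATM records
#' with residue name HOH/WAT/SOL.  Only ATOM/HETATM/MODEL/ENDMDL records are
#' interpreted; everything else is skipped.  No general-purpose structure
#' package is assumed.
#'
#' @param path path to a PDB file.
#' @param water_names residue names recognized as water.
#' @return a `conformer_ensemble`: list with `models` (list of atom
#'   data.frames sharing atom count and order) and `water_names`.
#' @export
read_pdb_ensemble <- function(path, water_names = c("HOH", "WAT", "SOL")) {
  lines <- readLines(path)
  frames <- list()
  block <- character(0)
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      block <- character(0)
    } else if (tag == "ENDMDL") {
      frames[[length(frames) + 1L]] <- block
      block <- character(0)
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      block <- c(block, ln)
    }
  }
  if (length(frames) == 0) {
    if (length(block) == 0) stop("no ATOM/HETATM records in ", path)
    frames <- list(block)
  }
  models <- lapply(frames, parse_pdb_atoms)
  nat <- vapply(models, nrow, integer(1))
  if (length(unique(nat)) != 1)
    stop("models differ in atom count: ", paste(unique(nat), collapse = ", "))
  new_conformer_ensemble(models, water_names)
}

parse_pdb_atoms <- function(lines) {
  num <- function(a, b) as.numeric(substr(lines, a, b))
  df <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = as.integer(substr(lines, 7, 11)),
    name = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resid = as.integer(substr(lines, 23, 26)),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE)
  blank <- df$element == "" | is.na(df$element)
  if (any(blank))   # infer element from the first alphabetic atom-name char
    df$element[blank] <- vapply(df$name[blank], function(nm) {
      ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
      if (length(ch)) toupper(ch) else "X"
    }, character(1))
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates in PDB input")
  df
}

new_conformer_ensemble <- function(models, water_names = c("HOH", "WAT", "SOL")) {
  if (length(models) < 1) stop("an ensemble needs at least one model")
  structure(list(models = models, water_names = water_names),
            class = "conformer_ensemble")
}

#' Assemble a conformer ensemble from atom tables
#'
#' @param models list of atom data.frames (equal atom count and order).
#' @param water_names residue names recognized as water.
#' @return a `conformer_ensemble`.
#' @export
conformer_ensemble <- function(models, water_names = c("HOH", "WAT", "SOL")) {
  nat <- vapply(models, nrow, integer(1))
  if (length(unique(nat)) != 1)
    stop("models differ in atom count")
  new_conformer_ensemble(models, water_names)
}

#' @rdname read_pdb_ensemble
#' @param ensemble a `conformer_ensemble`.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    df <- ensemble$models[[m]]
    nm <- ifelse(nchar(df$name) <= 3, sprintf(" %-3s", df$name),
                 sprintf("%-4s", df$name))
    writeLines(sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       df$record, df$serial, nm, df$resname,
                       ifelse(df$chain == "", "A", df$chain), df$resid,
                       df$x, df$y, df$z, 1.0, 0.0, df$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Atom selections on a structure frame
#'
#' @param frame an atom data.frame (one model of a `conformer_ensemble`).
#' @param what `"backbone"` (main-chain N, CA, C -- the clustering
#'   selection), `"protein"` (all non-water atoms), `"water"`, `"heavy"`
#'   (non-hydrogen), or `"all"`.
#' @param water_names residue names recognized as water.
#' @return logical mask over the rows of `frame`.
#' @export
select_atoms <- function(frame, what = c("backbone", "protein", "water",
                                         "heavy", "all"),
                         water_names = c("HOH", "WAT", "SOL")) {
  what <- match.arg(what)
  is_water <- frame$resname %in% water_names
  switch(what,
    backbone = !is_water & frame$name %in% c("N", "CA", "C"),
    protein = !is_water,
    water = is_water,
    heavy = frame$element != "H",
    all = rep(TRUE, nrow(frame)))
}

coords <- function(frame, mask = NULL) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  if (!is.null(mask)) m <- m[mask, , drop = FALSE]
  m
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  f <- x$models[[1]]
  nw <- length(unique(f$resid[select_atoms(f, "water", x$water_names)]))
  cat(sprintf("Conformer ensemble: %d models, %d atoms (%d waters per model)\n",
              length(x$models), nrow(f), nw))
  invisible(x)
}

# Standard atomic masses (g/mol) and Bondi-type van der Waals radii (A)
# used by radius_of_gyration() and sasa().
element_table <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "S", "P", "SE", "X"),
    mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 78.971, 12.011),
    vdw = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.90, NA),
    stringsAsFactors = FALSE)
}

element_property <- function(elements, property) {
  tab <- element_table()
  idx <- match(toupper(elements), tab$element)
  out <- tab[[property]][idx]
  if (property == "vdw" && any(is.na(out)))
    stop("no van der Waals radius configured for element(s): ",
         paste(unique(elements[is.na(out)]), collapse = ", "))
  if (property == "mass") out[is.na(out)] <- 12.011
  out
}
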