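# Internal fixed-format V2000 SDF reader/writer.
#
# The archive format and the toy-system emitters need single-atom molecules,
# which fall outside what the surrounding toolkits accept, so the (small)
# V2000 subset used here is implemented directly: atom block, bond block,
# old-style charge codes and ">  <tag>" data fields.

.charge_code_to_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1,
                            `4` = 0, `5` = -1, `6` = -2, `7` = -3)

.charge_to_code <- function(q) {
  code <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
  out <- code[as.character(q)]
  if (anyNA(out)) stop("formal charges outside [-3, 3] are not representable")
  unname(out)
}

# Parse the text of one or more concatenated SDF records.
parse_sdf_text <- function(lines) {
  if (length(lines) == 0L) stop("empty SDF input")
  # split on record terminators
  term <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, term + 1L)
  ends <- c(term - 1L, length(lines))
  if (length(term) == 0L) { starts <- 1L; ends <- length(lines) }
  recs <- list()
  for (k in seq_along(starts)) {
    if (starts[k] > ends[k]) next
    block <- lines[starts[k]:ends[k]]
    if (all(!nzchar(trimws(block)))) next
    recs[[length(recs) + 1L]] <- parse_sdf_record(block)
  }
  if (length(recs) == 0L) stop("no molecule records found in SDF input")
  recs
}

parse_sdf_record <- function(block) {
  if (length(block) < 4L) stop("truncated SDF record")
  counts <- block[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || is.na(n_bonds))
    stop("unparseable SDF counts line: ", counts)
  if (n_atoms < 1L) stop("SDF record with zero atoms")
  atom_lines <- block[4L + seq_len(n_atoms)]
  x <- as.numeric(substr(atom_lines, 1L, 10L))
  y <- as.numeric(substr(atom_lines, 11L, 20L))
  z <- as.numeric(substr(atom_lines, 21L, 30L))
  element <- trimws(substr(atom_lines, 31L, 34L))
  code <- trimws(substr(atom_lines, 37L, 39L))
  code[!nzchar(code)] <- "0"
  charge <- .charge_code_to_charge[code]
  charge[is.na(charge)] <- 0
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("unparseable atom coordinates in SDF record")
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (n_bonds > 0L) {
    bond_lines <- block[4L + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(
      i = as.integer(substr(bond_lines, 1L, 3L)),
      j = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  }
  # data fields:  >  <tag>  followed by value lines up to a blank line
  props <- character(0)
  rest <- block[-(seq_len(4L + n_atoms + n_bonds))]
  tag_idx <- grep("^>", rest)
  for (t in tag_idx) {
    tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", rest[t])
    vals <- character(0)
    p <- t + 1L
    while (p <= length(rest) && nzchar(trimws(rest[p])) &&
           !startsWith(rest[p], ">") && !startsWith(rest[p], "$$$$")) {
      vals <- c(vals, rest[p])
      p <- p + 1L
    }
    props[tag] <- paste(vals, collapse = "\n")
  }
  list(
    title = trimws(block[1L]),
    element = element,
    coords = cbind(x = x, y = y, z = z),
    charge = unname(charge),
    bonds = bonds,
    props = props
  )
}

read_sdf_file <- function(path) {
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  parse_sdf_text(readLines(path, warn = FALSE))
}

# records: list of list(title, element, coords, charge, bonds, props)
format_sdf_record <- function(rec) {
  n_atoms <- nrow(rec$coords)
  n_bonds <- if (is.null(rec$bonds)) 0L else nrow(rec$bonds)
  charge <- if (is.null(rec$charge)) rep(0L, n_atoms) else rec$charge
  out <- c(
    if (is.null(rec$title)) "" else rec$title,
    "  dockminima",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms, n_bonds)
  )
  out <- c(out, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
    rec$coords[, 1L], rec$coords[, 2L], rec$coords[, 3L],
    rec$element, .charge_to_code(charge)
  ))
  if (n_bonds > 0L) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                          rec$bonds$i, rec$bonds$j, rec$bonds$order))
  }
  out <- c(out, "M  END")
  if (length(rec$props) > 0L) {
    for (tag in names(rec$props)) {
      out <- c(out, sprintf(">  <%s>", tag), rec$props[[tag]], "")
    }
  }
  c(out, "$$$$")
}

write_sdf_file <- function(records, path) {
  lines <- unlist(lapply(records, format_sdf_record), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
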