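#' Read an MRC2014 volume
#'
#' Parses mode-2 (32-bit float) MRC2014 files. The axis order in the file
#' (MAPC/MAPR/MAPS) is honored: data are permuted so the returned array is
#' always indexed `[x, y, z]`. Pixel size is `CELLA / M`.
#'
#' @param path file path
#' @return a [density_volume()]
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024L)
  if (length(hdr_raw) < 1024L) stop("read_mrc: truncated header (not MRC)")
  int_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                "integer", 1L, 4L, endian = "little")
  num_at <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)],
                                "numeric", 1L, 4L, endian = "little")
  magic <- rawToChar(hdr_raw[(4 * 52 + 1):(4 * 52 + 4)])
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop("read_mrc: missing 'MAP ' magic; not an MRC2014 file")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  if (mode != 2L) stop(sprintf("read_mrc: unsupported mode %d (only mode 2)", mode))
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(num_at(11), num_at(12), num_at(13))
  mapcrs <- c(int_at(17), int_at(18), int_at(19))
  nsymbt <- int_at(24)
  origin <- c(num_at(50), num_at(51), num_at(52))
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  n <- as.double(nx) * ny * nz
  vals <- readBin(con, "numeric", n, 4L, endian = "little")
  if (length(vals) < n) stop("read_mrc: truncated data section")
  a <- array(vals, dim = c(nx, ny, nz)) # file order: column/row/section
  # map file axes (c, r, s) onto (x, y, z)
  if (!all(mapcrs == 1:3)) {
    if (!all(sort(mapcrs) == 1:3)) stop("read_mrc: invalid MAPC/MAPR/MAPS")
    perm <- match(1:3, mapcrs) # position of x, y, z among (c, r, s)
    a <- aperm(a, perm)
  }
  m_xyz <- c(mx, my, mz)
  px <- cella[1] / m_xyz[1]
  if (m_xyz[1] > 0 && any(abs(cella / m_xyz - px) > 1e-3 * px))
    warning("read_mrc: anisotropic pixel size; using the x spacing")
  density_volume(a, pixel_size = px, origin = origin)
}

#' Write an MRC2014 volume (mode 2 float)
#'
#' Axis order is written as MAPC/MAPR/MAPS = 1/2/3 (x fastest); a
#' write-then-read roundtrip is bit-identical for float data.
#'
#' @param vol a [density_volume()] (or a 3D array with `pixel_size`)
#' @param path output file path
#' @param pixel_size used when `vol` is a bare array
#' @return `path`, invisibly
#' @export
write_mrc <- function(vol, path, pixel_size = NULL) {
  if (!inherits(vol, "density_volume")) {
    stopifnot(!is.null(pixel_size))
    vol <- density_volume(vol, pixel_size)
  }
  d <- dim(vol$data)
  vals <- as.single_float <- as.numeric(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wi(d) # NX NY NZ
  wi(2L) # MODE
  wi(c(0L, 0L, 0L)) # NXSTART..
  wi(d) # MX MY MZ
  wf(d * vol$pixel_size) # CELLA
  wf(c(90, 90, 90)) # CELLB
  wi(1:3) # MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data))) # DMIN DMAX DMEAN
  wi(c(1L, 0L)) # ISPG, NSYMBT
  wi(rep(0L, 2)) # EXTRA 25-26
  writeBin(charToRaw("    "), con) # EXTTYP
  wi(20140L) # NVERSION
  wi(rep(0L, 21)) # EXTRA 29-49
  wf(vol$origin) # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # MACHST little-endian
  wf(sd(vol$data)) # RMS
  wi(0L) # NLABL
  writeBin(raw(800), con) # labels
  writeBin(vals, con, 4L, endian = "little")
  invisible(path)
}

aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M")

#' Atomic model container
#'
#' A light data.frame-backed container for coordinate records with the
#' per-atom tags used by the flexible-fitting machinery (coupling `regime`
#' in FULL/BACKBONE/DECOUPLED/FIXED, and `mobile` flag). Residue numbering
#' is taken verbatim; (chain, residue number, atom name) triples must be
#' unique.
#'
#' @param atoms data.frame with columns type, serial, atom, resname, chain,
#'   resno, x, y, z, occ, b, element (missing optional columns are filled)
#' @return object of class `atomic_model`
#' @export
atomic_model <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("atom", "resname", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atomic_model: missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(gsub("[0-9']", "", atoms$atom), 1, 1))
  if (is.null(atoms$regime)) atoms$regime <- "BACKBONE"
  if (is.null(atoms$mobile)) atoms$mobile <- TRUE
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atomic_model: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("atomic_model: duplicate (chain, residue, atom) records: ",
         paste(head(key[duplicated(key)], 3), collapse = "; "))
  structure(list(atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Atomic model: %d atoms, %d residues, chains %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = "")))
  invisible(x)
}

#' Coordinates of an atomic model as a matrix
#' @param model an [atomic_model()]
#' @param sel optional logical/integer row selection
#' @return n x 3 matrix
#' @export
model_coords <- function(model, sel = NULL) {
  a <- model$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Replace coordinates of an atomic model
#' @param model an [atomic_model()]
#' @param xyz n x 3 matrix
#' @return updated model
#' @export
set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

#' Read a PDB coordinate file
#'
#' Fixed-column ATOM/HETATM records parsed with bio3d; chain, residue and
#' atom identity are preserved, HETATM records retained (taggable as FIXED).
#'
#' @param path file path
#' @return an [atomic_model()]
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("read_pdb: ", conditionMessage(e)))
  a <- pdb$atom
  atomic_model(data.frame(
    type = a$type, serial = a$eleno, atom = a$elety, resname = a$resid,
    chain = ifelse(is.na(a$chain), " ", a$chain), resno = a$resno,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     toupper(substr(gsub("[0-9']", "", a$elety), 1, 1)),
                     a$elesy),
    stringsAsFactors = FALSE))
}

#' Write a PDB coordinate file
#'
#' Coordinates are preserved to the 3-decimal precision of the format.
#'
#' @param model an [atomic_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   type = a$type, eleno = a$serial, elety = a$atom,
                   resid = a$resname, chain = ifelse(a$chain == " ", "", a$chain),
                   resno = a$resno,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

#' Read a FASTA multiple sequence alignment
#'
#' All gapped sequences must share one length; the alphabet is restricted to
#' amino-acid codes plus the gap characters `-` and `.` (dots are converted
#' to dashes). Identifier order is preserved.
#'
#' @param path FASTA file
#' @return object of class `alignment_fasta`: list with `ids` and `seqs`
#'   (uppercase gapped strings)
#' @export
read_fasta_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (length(recs) < 1) stop("read_fasta_alignment: no sequences")
  seqs <- toupper(vapply(recs, as.character, ""))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("read_fasta_alignment: unequal gapped sequence lengths (",
         paste(range(lens), collapse = "-"), "); not an alignment")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYXBZJUO*-]", seqs)
  if (any(bad))
    stop("read_fasta_alignment: non amino-acid characters in: ",
         paste(head(names(recs)[bad], 3), collapse = ", "))
  structure(list(ids = names(recs), seqs = unname(seqs)),
            class = "alignment_fasta")
}

#' @export
print.alignment_fasta <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x$ids), nchar(x$seqs[1])))
  invisible(x)
}

# alignment as a character matrix (sequences x columns)
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Read a typed TSV table
#'
#' TSV with a header row; column types are inferred (int/float/string) and a
#' write-then-read roundtrip is lossless to 6+ significant digits.
#'
#' @param path file path
#' @return data.frame
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a TSV table
#' @param rows data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table_tsv <- function(rows, path) {
  write.table(format(rows, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
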