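#' Bead-model PDB I/O
#'
#' Bead models are exchanged as PDB-format files with one HETATM record per
#' bead: the bead radius is stored in the B-factor column and the scattering
#' weight in the occupancy column, coordinates in Angstrom. Note the PDB
#' fixed-column format carries three decimals (1e-3 A) of coordinate
#' precision and two decimals in the occupancy/B columns.
#'
#' @param model a [bead_model()].
#' @param file path to the PDB file.
#' @return `read_bead_pdb` returns a [bead_model()]; `write_bead_pdb`
#'   returns `file` invisibly.
#' @export
write_bead_pdb <- function(model, file) {
  stopifnot(inherits(model, "bead_model"))
  b <- model$beads
  xyz <- as.vector(t(as.matrix(b[, c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz, type = rep("HETATM", nrow(b)),
                   resno = seq_len(nrow(b)), resid = rep("BEA", nrow(b)),
                   eleno = seq_len(nrow(b)), elety = rep("C", nrow(b)),
                   o = b$weight, b = b$radius)
  invisible(file)
}

#' @rdname write_bead_pdb
#' @export
read_bead_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atom records in ", file)
  if (any(!is.finite(at$b)) || any(at$b <= 0))
    stop("invalid bead radii (B column) in ", file)
  bead_model(at$x, at$y, at$z, radius = at$b, weight = at$o,
             label = basename(file))
}

#' Scattering-curve text I/O
#'
#' Three-column whitespace-delimited text (q, I, sigma; sigma optional),
#' with header lines prefixed by `#`. Headers are preserved across a
#' write/read round trip. Files with non-monotone q or inconsistent column
#' counts are rejected with line-numbered errors.
#'
#' @param curve a [scattering_curve()].
#' @param file path.
#' @param header optional character vector of header lines (without the
#'   leading `#`).
#' @export
write_scattering <- function(curve, file, header = attr(curve, "header")) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(file, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  m <- if (is.null(curve$sigma)) cbind(curve$q, curve$I)
       else cbind(curve$q, curve$I, curve$sigma)
  utils::write.table(format(m, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_scattering
#' @export
read_scattering <- function(file) {
  lines <- readLines(file)
  is_head <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  header <- sub("^\\s*#\\s?", "", lines[grepl("^\\s*#", lines)])
  data_lines <- which(!is_head)
  if (length(data_lines) == 0L) stop("no data rows in ", file)
  fields <- strsplit(trimws(lines[data_lines]), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !ncol %in% 2:3)
    stop("inconsistent column counts in ", file, " (first bad line ",
         data_lines[which(lengths(fields) != lengths(fields)[1])[1]], ")")
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = ncol, byrow = TRUE))
  bad <- which(rowSums(is.na(vals)) > 0)
  if (length(bad)) stop("non-numeric data at line ", data_lines[bad[1]],
                        " of ", file)
  if (any(diff(vals[, 1]) <= 0))
    stop("q values not strictly increasing in ", file, " (line ",
         data_lines[which(diff(vals[, 1]) <= 0)[1] + 1L], ")")
  crv <- scattering_curve(vals[, 1], vals[, 2],
                          sigma = if (ncol == 3) vals[, 3] else NULL)
  if (length(header)) attr(crv, "header") <- header
  crv
}

#' p(r) text I/O
#'
#' Two-column (r, p) whitespace text with `#` headers, the conventional
#' exchange format for distance distributions.
#'
#' @param dd a [distance_distribution()].
#' @param file path.
#' @export
write_pr <- function(dd, file) {
  stopifnot(inherits(dd, "distance_distribution"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(sprintf("# Dmax %.17g", dd$Dmax), con)
  utils::write.table(format(cbind(dd$r, dd$p), digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_pr
#' @export
read_pr <- function(file) {
  lines <- readLines(file)
  dm <- grep("^#\\s*Dmax", lines, value = TRUE)
  heads <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  vals <- do.call(rbind, lapply(strsplit(trimws(lines[!heads]), "\\s+"),
                                as.numeric))
  Dmax <- if (length(dm)) as.numeric(sub("^#\\s*Dmax\\s+", "", dm[1]))
          else max(vals[, 1])
  distance_distribution(vals[, 1], vals[, 2], Dmax)
}

#' Sedimentation-equilibrium CSV I/O
#'
#' CSV with two columns (`r_cm`, `signal`) and metadata header rows of the
#' form `# key value` (`omega_rpm`, `temperature_C`, `rho`, `r_ref_cm`).
#'
#' @param dataset an `se_dataset`.
#' @param file path.
#' @export
write_se_csv <- function(dataset, file) {
  stopifnot(inherits(dataset, "se_dataset"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(sprintf("# omega_rpm %.10g", dataset$omega * 60 / (2 * pi)),
               sprintf("# temperature_C %.10g", dataset$T - 273.15),
               sprintf("# rho %.10g", dataset$rho),
               sprintf("# r_ref_cm %.10g", dataset$r_ref),
               "r_cm,signal"), con)
  utils::write.table(cbind(format(dataset$r, digits = 17, trim = TRUE),
                           format(dataset$signal, digits = 17, trim = TRUE)),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_se_csv
#' @export
read_se_csv <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
    if (length(parts) >= 2) meta[[parts[1]]] <- as.numeric(parts[2])
  }
  need <- c("omega_rpm", "temperature_C", "rho", "r_ref_cm")
  if (!all(need %in% names(meta)))
    stop("missing metadata header(s) in ", file, ": ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- body[-1]                      # column header row
  vals <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  if (ncol(vals) != 2) stop("expected 2 CSV columns in ", file)
  structure(list(r = vals[, 1], signal = vals[, 2],
                 omega = rpm_to_omega(meta$omega_rpm),
                 T = meta$temperature_C + 273.15, rho = meta$rho,
                 r_ref = meta$r_ref_cm, baseline_true = NA_real_),
            class = "se_dataset")
}

#' Unfolding-curve CSV I/O
#'
#' CSV with columns `c_gdmcl`, `signal` and an optional `# channel` header.
#'
#' @param curve an [unfolding_curve()].
#' @param file path.
#' @export
write_unfolding_csv <- function(curve, file) {
  stopifnot(inherits(curve, "unfolding_curve"))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c(paste("# channel", curve$channel), "c_gdmcl,signal"), con)
  utils::write.table(cbind(format(curve$c, digits = 17, trim = TRUE),
                           format(curve$y, digits = 17, trim = TRUE)),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_unfolding_csv
#' @export
read_unfolding_csv <- function(file) {
  lines <- readLines(file)
  ch <- grep("^#\\s*channel", lines, value = TRUE)
  channel <- if (length(ch)) sub("^#\\s*channel\\s+", "", ch[1]) else "signal"
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))][-1]
  vals <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  if (ncol(vals) != 2) stop("expected 2 CSV columns in ", file)
  unfolding_curve(vals[, 1], vals[, 2], channel)
}
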