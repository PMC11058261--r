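# Delimited-text file dialects. Every file is a `# key: value` metadata
# header block followed by a comma- or tab-separated table; the separator is
# auto-detected from the column-name line. All numbers use `.` decimals.

read_header_block <- function(lines) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    if (!grepl("^#", ln)) break
    i <- i + 1L
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)\\s*$", ln))[[1L]]
    if (length(m) == 3L) hdr[[trimws(m[2L])]] <- trimws(m[3L])
  }
  list(meta = hdr, n_skip = i)
}

detect_sep <- function(line) if (grepl("\t", line)) "\t" else ","

read_body <- function(path, n_skip) {
  lines <- readLines(path)
  body <- lines[(n_skip + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  sep <- detect_sep(body[1L])
  con <- textConnection(body)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stop_domain("malformed table in ", path, ": ",
                                    conditionMessage(e)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(trimws(df[[j]])))
    if (length(bad))
      stop_domain("malformed row in ", path, ": non-numeric value '",
                  df[bad[1L], j], "' in column '", names(df)[j],
                  "' (data line ", bad[1L], ")")
    df[[j]] <- v
  }
  df
}

require_meta <- function(meta, keys, path) {
  missing <- setdiff(keys, names(meta))
  if (length(missing))
    stop_domain("missing mandatory metadata key '", missing[1L], "' in ", path)
}

num_meta <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
}

fmt <- function(x) sprintf("%.8g", x)

#' Write a spectrum to a delimited-text file
#'
#' Long format: a `# key: value` header (label, pH, conc_uM, path_cm when
#' present) followed by `wavelength_nm,absorbance`.
#'
#' @param spec a [spectrum()]
#' @param path output file
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  hdr <- character(0)
  if (!is.null(spec$meta$label)) hdr <- c(hdr, paste0("# label: ", spec$meta$label))
  if (!is.null(spec$meta$pH)) hdr <- c(hdr, paste0("# pH: ", fmt(as.numeric(spec$meta$pH))))
  if (!is.null(spec$meta$conc_uM)) hdr <- c(hdr, paste0("# conc_uM: ", fmt(as.numeric(spec$meta$conc_uM))))
  hdr <- c(hdr, paste0("# path_cm: ", fmt(spec$path_length)))
  body <- c("wavelength_nm,absorbance",
            paste(fmt(spec$wavelengths), fmt(spec$absorbance), sep = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read spectra from a delimited-text file
#'
#' Accepts the long format of [write_spectrum()] (columns `wavelength_nm`,
#' `absorbance`) and a wide variant with one column per sample, where header
#' keys may carry comma-separated per-column values (e.g.
#' `# pH: 2, 2.5, 3`). Returns a list of [spectrum()] objects (length one for
#' the long format).
#'
#' @param path input file
#' @return list of [spectrum()] objects
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  hb <- read_header_block(lines)
  df <- read_body(path, hb$n_skip)
  if (!"wavelength_nm" %in% names(df))
    stop_domain("missing 'wavelength_nm' column in ", path)
  w <- df$wavelength_nm
  if (!is_uniform_grid(w))
    stop_domain("wavelength grid in ", path,
                " is not strictly increasing with a uniform step")
  path_cm <- num_meta(hb$meta, "path_cm", 1)
  sample_cols <- setdiff(names(df), "wavelength_nm")
  if (identical(sample_cols, "absorbance")) {
    meta <- list(label = hb$meta$label %||% basename(path))
    if (!is.null(hb$meta$pH)) meta$pH <- as.numeric(hb$meta$pH)
    if (!is.null(hb$meta$conc_uM)) meta$conc_uM <- as.numeric(hb$meta$conc_uM)
    return(list(spectrum(w, df$absorbance, path_cm, meta)))
  }
  split_vals <- function(key) {
    if (is.null(hb$meta[[key]])) return(NULL)
    as.numeric(trimws(strsplit(hb$meta[[key]], ",")[[1L]]))
  }
  pHs <- split_vals("pH"); concs <- split_vals("conc_uM")
  lapply(seq_along(sample_cols), function(j) {
    meta <- list(label = sample_cols[j])
    if (!is.null(pHs)) meta$pH <- pHs[j]
    if (!is.null(concs)) meta$conc_uM <- concs[j]
    spectrum(w, df[[sample_cols[j]]], path_cm, meta)
  })
}

#' Read every spectra file in a directory into a titration series
#'
#' @param dir directory of spectra files (`*.csv`, `*.tsv`, `*.txt`)
#' @return a [titration_series()]
#' @export
read_titration_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE))
  files <- files[!grepl("manifest", files)]
  if (!length(files)) stop_domain("no spectra files found in ", dir)
  titration_series(unlist(lapply(files, read_spectra), recursive = FALSE))
}

#' Write / read an extinction spectrum (`wavelength_nm,epsilon_mM_cm`)
#'
#' @param eps an [extinction_spectrum()]
#' @param path file path
#' @export
write_extinction <- function(eps, path) {
  stopifnot(inherits(eps, "extinction_spectrum"))
  hdr <- c(paste0("# species: ", eps$species),
           paste0("# protonation_state: ", eps$protonation_state))
  body <- c("wavelength_nm,epsilon_mM_cm",
            paste(fmt(eps$wavelengths), fmt(eps$epsilon), sep = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_extinction
#' @return `read_extinction`: an [extinction_spectrum()]
#' @export
read_extinction <- function(path) {
  lines <- readLines(path)
  hb <- read_header_block(lines)
  df <- read_body(path, hb$n_skip)
  if (!all(c("wavelength_nm", "epsilon_mM_cm") %in% names(df)))
    stop_domain("extinction file ", path,
                " must have columns wavelength_nm, epsilon_mM_cm")
  extinction_spectrum(df$wavelength_nm, df$epsilon_mM_cm,
                      species = hb$meta$species %||% "",
                      protonation_state = hb$meta$protonation_state %||%
                        "apparent-at-pH")
}

#' Write a two-wavelength time course to a delimited-text file
#'
#' Header keys: `X0_uM`, `Rib1P_uM`, `N7X0_uM`, `Pi0_uM`, `enzyme_gL`,
#' `enzyme_uM`, `pH`, `path_cm`; columns `time_s, A300, A288` (named after
#' the default analysis/control wavelengths).
#'
#' @param tc a [timecourse()]
#' @param path output file
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  cd <- tc$conditions
  hdr <- c(paste0("# X0_uM: ", fmt(cd$X0)),
           paste0("# Rib1P_uM: ", fmt(cd$R0)),
           paste0("# N7X0_uM: ", fmt(cd$N0)),
           paste0("# Pi0_uM: ", fmt(cd$P0)))
  if (is.finite(cd$enzyme_gL)) hdr <- c(hdr, paste0("# enzyme_gL: ", fmt(cd$enzyme_gL)))
  if (is.finite(cd$enzyme_uM)) hdr <- c(hdr, paste0("# enzyme_uM: ", fmt(cd$enzyme_uM)))
  if (is.finite(cd$pH)) hdr <- c(hdr, paste0("# pH: ", fmt(cd$pH)))
  hdr <- c(hdr, paste0("# path_cm: ", fmt(cd$path_length)))
  body <- c("time_s,A300,A288",
            paste(fmt(tc$times), fmt(tc$A_analysis), fmt(tc$A_control), sep = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a time course (or a directory of them)
#'
#' @param path a time-course file
#' @return a [timecourse()]
#' @export
read_timecourse <- function(path) {
  lines <- readLines(path)
  hb <- read_header_block(lines)
  require_meta(hb$meta, c("X0_uM", "path_cm"), path)
  df <- read_body(path, hb$n_skip)
  if (!all(c("time_s", "A300", "A288") %in% names(df)))
    stop_domain("time-course file ", path,
                " must have columns time_s, A300, A288")
  if (any(diff(df$time_s) <= 0))
    stop_domain("time column in ", path, " is not strictly increasing")
  cond <- reaction_conditions(
    X0 = num_meta(hb$meta, "X0_uM"),
    R0 = num_meta(hb$meta, "Rib1P_uM", 0),
    N0 = num_meta(hb$meta, "N7X0_uM", 0),
    P0 = num_meta(hb$meta, "Pi0_uM", 0),
    enzyme_gL = num_meta(hb$meta, "enzyme_gL"),
    enzyme_uM = num_meta(hb$meta, "enzyme_uM"),
    pH = num_meta(hb$meta, "pH"),
    path_length = num_meta(hb$meta, "path_cm"))
  timecourse(df$time_s, df$A300, df$A288, cond)
}

#' @rdname read_timecourse
#' @param dir directory of time-course files
#' @return `read_timecourses`: list of [timecourse()] objects
#' @export
read_timecourses <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE))
  files <- files[!grepl("manifest", files)]
  if (!length(files)) stop_domain("no time-course files found in ", dir)
  lapply(files, read_timecourse)
}

#' Write / read an excitation table
#'
#' One row per excitation: columns `structure, energy_rel_kJmol,
#' excitation_eV, oscillator_strength`.
#'
#' @param states list of [tautomer_states()] objects
#' @param path file path
#' @export
write_excitations <- function(states, path) {
  rows <- lapply(states, function(s) {
    data.frame(structure = s$label, energy_rel_kJmol = s$energy_rel,
               excitation_eV = s$excitations$energy_ev,
               oscillator_strength = s$excitations$strength)
  })
  df <- do.call(rbind, rows)
  lines <- c("structure,energy_rel_kJmol,excitation_eV,oscillator_strength",
             paste(df$structure, fmt(df$energy_rel_kJmol),
                   fmt(df$excitation_eV), fmt(df$oscillator_strength),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_excitations
#' @return `read_excitations`: list of [tautomer_states()] objects
#' @export
read_excitations <- function(path) {
  lines <- readLines(path)
  hb <- read_header_block(lines)
  body <- lines[(hb$n_skip + 1L):length(lines)]
  sep <- detect_sep(body[1L])
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("structure", "energy_rel_kJmol", "excitation_eV",
            "oscillator_strength")
  if (!all(need %in% names(df)))
    stop_domain("excitation table ", path, " must have columns ",
                paste(need, collapse = ", "))
  for (col in need[-1L]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop_domain("malformed row in ", path, ": non-numeric '", col,
                  "' at data line ", which(is.na(v))[1L])
    df[[col]] <- v
  }
  lapply(split(df, df$structure), function(g) {
    tautomer_states(g$structure[1L], g$energy_rel_kJmol[1L],
                    data.frame(energy_ev = g$excitation_eV,
                               strength = g$oscillator_strength))
  })
}
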