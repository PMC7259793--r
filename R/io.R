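#' Parse a per-participant trial-file name
#'
#' File names encode the participant and condition, e.g.
#' \code{subj1_sig_g = 0.1.txt} or
#' \code{subj8_sig_pi = 0.5_sig_g = 0.1.txt}. Spaces around \code{"="} are
#' tolerated; \code{sig_pi} defaults to 0.1 when absent. Written files use the
#' normalised spelling without spaces.
#'
#' @param name file name (with or without directory).
#' @return List with \code{participant}, \code{sigma_pi}, \code{sigma_g}, or
#'   \code{NULL} if the name does not follow the convention.
#' @export
parse_s1_filename <- function(name) {
  base <- sub("\\.txt$", "", basename(name))
  m <- regexec("^(.*?)_sig_(pi|g)\\s*=\\s*([0-9.eE+-]+?)(?:_sig_g\\s*=\\s*([0-9.eE+-]+))?$",
               base, perl = TRUE)
  parts <- regmatches(base, m)[[1L]]
  if (!length(parts)) return(NULL)
  if (parts[3] == "pi") {
    if (is.na(parts[5]) || parts[5] == "") return(NULL)
    list(participant = parts[2], sigma_pi = as.numeric(parts[4]),
         sigma_g = as.numeric(parts[5]))
  } else {
    list(participant = parts[2], sigma_pi = 0.1,
         sigma_g = as.numeric(parts[4]))
  }
}

s1_filename <- function(participant, sigma_pi, sigma_g) {
  if (isTRUE(all.equal(sigma_pi, 0.1))) {
    sprintf("%s_sig_g=%s.txt", participant, format(sigma_g))
  } else {
    sprintf("%s_sig_pi=%s_sig_g=%s.txt", participant, format(sigma_pi),
            format(sigma_g))
  }
}

#' Read an 11-column per-participant trial file
#'
#' The dialect has one row per trial with 11 whitespace- (or comma-)
#' separated numeric fields: the four x then four y stimulus coordinates, the
#' stimulus index \eqn{j}, the generating quadratic parameter \eqn{w_j}, and
#' the participant's response. Condition and participant are read from the
#' file name convention (see [parse_s1_filename()]) unless supplied
#' explicitly.
#'
#' @param path path to the trial file.
#' @param participant,sigma_pi,sigma_g overrides when the file name does not
#'   follow the convention (then all three are required).
#' @return A trial data frame in the [simulate_observer()] schema. Rows of
#'   the \eqn{\sigma_g = 0} condition are flagged as practice.
#' @export
read_trials <- function(path, participant = NULL, sigma_pi = NULL,
                        sigma_g = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  meta <- parse_s1_filename(path)
  if (is.null(meta)) {
    if (is.null(participant) || is.null(sigma_pi) || is.null(sigma_g))
      stop(sprintf(
        "cannot parse condition from file name '%s'; supply participant, sigma_pi and sigma_g",
        basename(path)))
    meta <- list(participant = participant, sigma_pi = sigma_pi,
                 sigma_g = sigma_g)
  } else {
    if (!is.null(participant)) meta$participant <- participant
    if (!is.null(sigma_pi)) meta$sigma_pi <- sigma_pi
    if (!is.null(sigma_g)) meta$sigma_g <- sigma_g
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "[,\\s]+", perl = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 11L || any(is.na(vals)))
      stop(sprintf("malformed row at line %d of %s: expected 11 numeric fields",
                   i, basename(path)))
    vals
  })
  m <- do.call(rbind, rows)
  j <- m[, 9L]
  if (any(j != round(j) | j < 1))
    stop(sprintf("stimulus indices in %s must be positive integers",
                 basename(path)))
  data.frame(participant = meta$participant, sigma_pi = meta$sigma_pi,
             sigma_g = meta$sigma_g, practice = meta$sigma_g == 0,
             j = as.integer(j),
             x1 = m[, 1L], x2 = m[, 2L], x3 = m[, 3L], x4 = m[, 4L],
             y1 = m[, 5L], y2 = m[, 6L], y3 = m[, 7L], y4 = m[, 8L],
             w_true = m[, 10L], response = m[, 11L])
}

#' Read every trial file in a directory
#'
#' @param dir directory holding \code{*.txt} trial files (searched
#'   recursively, matching the deposited one-folder-per-participant layout).
#' @return A single combined trial data frame.
#' @export
read_trials_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE,
                      recursive = TRUE)
  files <- files[!vapply(files, function(f) is.null(parse_s1_filename(f)),
                         logical(1))]
  if (!length(files)) stop(sprintf("no trial files found under %s", dir))
  out <- do.call(rbind, lapply(files, read_trials))
  rownames(out) <- NULL
  out
}

#' Write trial data in the 11-column dialect
#'
#' One file per participant x condition, named with the normalised convention
#' (\code{<participant>_sig_g=<v>.txt}, plus \code{sig_pi} when it differs
#' from 0.1). Numbers are written at full double precision so a write/read
#' round trip is lossless; synthetic experiments written this way are
#' interchangeable with deposited data downstream.
#'
#' @param trials trial data frame.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_trials <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- interaction(trials$participant, trials$sigma_pi, trials$sigma_g,
                     drop = TRUE)
  paths <- character(0)
  for (d in split(trials, key)) {
    path <- file.path(dir, s1_filename(d$participant[1], d$sigma_pi[1],
                                       d$sigma_g[1]))
    m <- as.matrix(d[, c("x1", "x2", "x3", "x4", "y1", "y2", "y3", "y4",
                         "j", "w_true", "response")])
    lines <- apply(m, 1L, function(v) paste(sprintf("%.17g", v),
                                            collapse = " "))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Export a model comparison as tidy CSV files
#'
#' @param cmp a [compare_all()] result.
#' @param dir output directory.
#' @return Invisibly, the written file paths.
#' @export
write_comparison_csv <- function(cmp, dir) {
  stopifnot(inherits(cmp, "model_comparison"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "log_likelihoods.csv")
  p2 <- file.path(dir, "group_deltas.csv")
  utils::write.csv(cmp$per_participant, p1, row.names = FALSE)
  utils::write.csv(cmp$group, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
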