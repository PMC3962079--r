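# Scattering profiles as tidy tables: q (1/A), intensity, optional sigma.

#' Construct a scattering profile
#'
#' @param q Ascending momentum-transfer grid, 1/Angstrom.
#' @param intensity Non-negative intensities (arbitrary units).
#' @param sigma Optional per-point uncertainties (> 0).
#' @param engine Optional label recording which engine produced it.
#' @return A tibble of class `saxs_profile` with columns `q`, `intensity`
#'   and (when given) `sigma`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, engine = NULL) {
  stopifnot(length(q) == length(intensity))
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q grid must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    out$sigma <- as.numeric(sigma)
  }
  class(out) <- c("saxs_profile", class(tibble::tibble()))
  attr(out, "engine") <- engine
  out
}

#' @export
print.saxs_profile <- function(x, ...) {
  eng <- attr(x, "engine")
  cat(sprintf("<saxs_profile> %d points, q in [%.4g, %.4g] 1/A%s\n",
              nrow(x), min(x$q), max(x$q),
              if (is.null(eng)) "" else paste0(" [", eng, "]")))
  NextMethod()
}

#' Read a SAXS profile from text
#'
#' Whitespace-separated columns q, I and optionally sigma; `#` starts a
#' comment. Two-column files are accepted with sigma set to 1% of I
#' (a loud warning is raised, since the chi score needs uncertainties).
#' A CSV dialect with a `q,intensity[,sigma]` header is also read.
#'
#' @param path File path.
#' @param s_convention Set `TRUE` if the first column is
#'   s = 2 sin(theta)/lambda; it is converted via q = 2 pi s.
#' @return A `saxs_profile`.
#' @export
read_profile <- function(path, s_convention = FALSE) {
  if (!file.exists(path)) stop("profile file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1)
  if (grepl("^\\s*\"?q\"?\\s*,", first)) {
    df <- utils::read.csv(path, comment.char = "#")
  } else {
    df <- utils::read.table(path, comment.char = "#")
  }
  if (ncol(df) < 2) stop("profile needs at least 2 columns (q, I)",
                         call. = FALSE)
  names(df)[1:2] <- c("q", "intensity")
  q <- df$q
  if (s_convention) q <- 2 * pi * q
  sigma <- if (ncol(df) >= 3) df[[3]] else NULL
  if (is.null(sigma)) {
    warning("no uncertainty column in ", basename(path),
            "; assigning sigma = 0.01 * I", call. = FALSE)
    sigma <- 0.01 * df$intensity
  }
  saxs_profile(q, df$intensity, sigma)
}

#' Write a profile to 3-column text
#'
#' q, I and (when present) sigma, whitespace-separated, with a `#` header.
#' `format = "csv"` writes the documented CSV dialect instead.
#'
#' @param profile A `saxs_profile`.
#' @param path Output path.
#' @param format `"dat"` (whitespace) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("dat", "csv")) {
  format <- match.arg(format)
  has_sigma <- "sigma" %in% names(profile)
  if (format == "csv") {
    utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- if (has_sigma) "# q intensity sigma" else "# q intensity"
  body <- if (has_sigma) {
    sprintf("%.6e %.6e %.6e", profile$q, profile$intensity, profile$sigma)
  } else {
    sprintf("%.6e %.6e", profile$q, profile$intensity)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
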