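#' Write a flash-transient set to CSV
#'
#' Long format: columns `flash` (1-based), `channel`, `time_s`, `value`,
#' one row per sample. A metadata sidecar JSON (`<path>.json`) records the
#' temperature, flash spacing, flash energies and seed.
#'
#' @param x `flash_transient_set`.
#' @param path Output CSV path.
#' @param digits Number of significant digits written (default full
#'   precision via 17 digits).
#' @return `path`, invisibly.
#' @export
write_flash_transients <- function(x, path, digits = 17) {
  stopifnot(inherits(x, "flash_transient_set"))
  nf <- dim(x$signal)[1]; nc <- dim(x$signal)[2]; nt <- dim(x$signal)[3]
  df <- data.frame(
    flash = rep(seq_len(nf), times = nc * nt),
    channel = rep(rep(x$channels, each = nf), times = nt),
    time_s = rep(x$time, each = nf * nc),
    value = as.vector(x$signal))
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  out <- data.frame(flash = df$flash, channel = df$channel,
                    time_s = fmt(df$time_s), value = fmt(df$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- c(x$metadata, list(flash_energies = x$flash_energies,
                             channels = x$channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a flash-transient set from CSV
#'
#' Reads the long dialect written by [write_flash_transients()] (columns
#' `flash`, `channel`, `time_s`, `value`) or a wide dialect (`time_s` plus
#' one column per channel, one file per flash; pass all per-flash files in
#' order). Parsing is strict: missing columns, duplicated time stamps,
#' non-monotone time and differing grids across flashes are errors, not
#' warnings.
#'
#' @param path CSV path (long format) or character vector of per-flash
#'   paths (wide format).
#' @param format `"long"` or `"wide"`.
#' @return `flash_transient_set`.
#' @export
read_flash_transients <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    df <- utils::read.csv(path[1L], stringsAsFactors = FALSE)
    need <- c("flash", "channel", "time_s", "value")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("missing column(s) in ", path[1L], ": ",
           paste(miss, collapse = ", "))
    }
    if (anyNA(df$time_s) || anyNA(df$value)) {
      stop("malformed rows (NA time or value) in ", path[1L])
    }
    key <- paste(df$flash, df$channel, df$time_s)
    if (anyDuplicated(key)) {
      stop("duplicated time stamp at row ",
           which(duplicated(key))[1L], " of ", path[1L])
    }
    flashes <- sort(unique(df$flash))
    channels <- unique(df$channel)
    time <- sort(unique(df$time_s))
    if (any(diff(time) <= 0)) stop("non-monotone time grid")
    nf <- length(flashes); nc <- length(channels); nt <- length(time)
    if (nrow(df) != nf * nc * nt) {
      stop("mixed time grids: expected ", nf * nc * nt,
           " rows for a complete flash x channel x time grid, found ",
           nrow(df))
    }
    sig <- array(NA_real_, c(nf, nc, nt))
    fi <- match(df$flash, flashes)
    ci <- match(df$channel, channels)
    ti <- match(df$time_s, time)
    sig[cbind(fi, ci, ti)] <- df$value
    if (anyNA(sig)) stop("incomplete flash x channel x time grid")
    meta_path <- paste0(path[1L], ".json")
    meta <- if (file.exists(meta_path)) {
      jsonlite::read_json(meta_path, simplifyVector = TRUE)
    } else list()
    flash_transient_set(
      time, sig, channels = channels,
      flash_energies = meta$flash_energies,
      temperature_K = if (is.null(meta$temperature_K)) NA_real_
                      else as.numeric(meta$temperature_K),
      flash_spacing_s = if (is.null(meta$flash_spacing_s)) 1
                        else meta$flash_spacing_s,
      seed = if (is.null(meta$seed) || is.na(meta$seed)) NA_integer_
             else as.integer(meta$seed))
  } else {
    tabs <- lapply(path, function(p) {
      df <- utils::read.csv(p, stringsAsFactors = FALSE)
      if (!"time_s" %in% names(df)) {
        stop("missing `time_s` column in ", p)
      }
      if (anyDuplicated(df$time_s)) {
        stop("duplicated time stamp at row ",
             which(duplicated(df$time_s))[1L], " of ", p)
      }
      if (any(diff(df$time_s) <= 0)) stop("non-monotone time in ", p)
      df
    })
    time <- tabs[[1L]]$time_s
    channels <- setdiff(names(tabs[[1L]]), "time_s")
    for (i in seq_along(tabs)) {
      if (!isTRUE(all.equal(tabs[[i]]$time_s, time, tolerance = 1e-12))) {
        stop("time grid of ", path[i], " differs from ", path[1L])
      }
    }
    sig <- array(NA_real_, c(length(tabs), length(channels), length(time)))
    for (i in seq_along(tabs)) {
      sig[i, , ] <- t(as.matrix(tabs[[i]][, channels, drop = FALSE]))
    }
    flash_transient_set(time, sig, channels = channels)
  }
}

#' Write an analysis report as JSON
#'
#' Serializes a result object (an `eyring_result`, `arrhenius_fit`,
#' `multiexp_fit`, `o2_fit`, or any plain list of numbers) to JSON with
#' full-precision numbers plus a `display` block rounded in the convention
#' of published tables: energies to 1 meV, time constants to 3 significant
#' figures.
#'
#' @param x Result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  body <- report_list(x)
  display <- list()
  for (nm in names(body)) {
    v <- body[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) next
    display[[nm]] <- if (grepl("meV$", nm)) round(v)
                     else if (grepl("_s$", nm)) signif(v, 3)
                     else signif(v, 4)
  }
  jsonlite::write_json(c(body, list(display = display)), path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Report path written by [write_report()].
#' @return Named list (the full-precision body; the `display` block is
#'   kept as an element).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# flatten result objects into a named list of scalars for reporting
report_list <- function(x) {
  if (inherits(x, "eyring_result")) {
    list(type = "eyring_result",
         dH_meV = x$dH_meV, dG_meV = x$dG_meV,
         negTdS_meV = x$negT0dS_meV,
         Ea_meV = x$Ea_meV, tau_s = x$tau_s, T0_K = x$T0_K)
  } else if (inherits(x, "arrhenius_fit")) {
    list(type = "arrhenius_fit",
         Ea_meV = x$Ea_meV, lnA = x$lnA,
         se_Ea_meV = x$se_Ea_meV, se_lnA = x$se_lnA)
  } else if (inherits(x, "multiexp_fit")) {
    out <- list(type = "multiexp_fit",
                ssr = x$ssr, convergence = x$convergence)
    for (i in seq_along(x$taus)) {
      out[[paste0("tau", i, "_s")]] <- x$taus[i]
      out[[paste0("se_tau", i, "_s")]] <- x$tau_se[i]
    }
    out$amplitudes <- x$amplitudes
    out$y0 <- x$y0
    out
  } else if (inherits(x, "o2_fit")) {
    list(type = "o2_fit",
         tau_pre_s = x$tau_pre, tau_o2_s = x$tau_o2,
         se_tau_pre_s = x$se_tau_pre, se_tau_o2_s = x$se_tau_o2,
         amplitude = x$amplitude, ssr = x$ssr,
         weakly_identified = x$weakly_identified)
  } else if (is.list(x)) {
    x
  } else {
    stop("no report serialization for class ",
         paste(class(x), collapse = "/"))
  }
}
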