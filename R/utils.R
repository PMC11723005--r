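# shared internal helpers

# two-level significance convention used throughout the trial reports:
# "*" p < 0.05, "**" p < 0.01, "ns" otherwise
stars_from_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = "ns"
  )
}

# "2-3" / "16-18" -> integer age vectors; single ages ("7") allowed
parse_age_window <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  parts <- suppressWarnings(as.integer(parts))
  if (anyNA(parts) || length(parts) > 2L) {
    abort(paste0("cannot parse age window '", label, "'"))
  }
  if (length(parts) == 1L) parts else seq(parts[1], parts[2])
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(paste0(
      what, " is missing required column",
      if (length(missing) > 1L) "s" else "", ": ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

check_cross_type <- function(x) {
  ok <- x %in% c("DxM", "MxD")
  if (!all(ok)) {
    abort(paste0(
      "cross_type must be 'DxM' or 'MxD'; found: ",
      paste(unique(x[!ok]), collapse = ", ")
    ))
  }
  invisible(x)
}
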