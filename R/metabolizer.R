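# CYP2D6 metabolizer parameters: hazard ratio of the decreased-metabolizer
# (DM) group relative to extensive metabolizers (EM), and the DM frequency.

#' Construct metabolizer parameters
#'
#' Bundles the two pharmacogenetic parameters of the model: `hr_dm`, the
#' proportional-hazards ratio of decreased metabolizers (DM = hetEM/IM +
#' PM) relative to extensive metabolizers (EM, which include ultra-rapid
#' metabolizers) on tamoxifen, and `f_dm`, the population frequency of DM.
#'
#' @param hr_dm Hazard ratio of DM vs EM; strictly positive. Base cases:
#'   1.29 for the DFS endpoint, 1.33 for EFS.
#' @param f_dm DM frequency in `[0, 1]`; base case 0.54.
#' @return An object of class `metabolizer_params`.
#' @export
#' @examples
#' metabolizer_params(1.29, 0.54)
metabolizer_params <- function(hr_dm, f_dm) {
  stopifnot(is.numeric(hr_dm), length(hr_dm) == 1L,
            is.numeric(f_dm), length(f_dm) == 1L)
  if (is.na(hr_dm) || hr_dm <= 0) {
    stop("hr_dm must be > 0, got ", format(hr_dm))
  }
  if (is.na(f_dm) || f_dm < 0 || f_dm > 1) {
    stop("f_dm must lie in [0, 1], got ", format(f_dm))
  }
  structure(list(hr_dm = hr_dm, f_dm = f_dm), class = "metabolizer_params")
}

#' @export
print.metabolizer_params <- function(x, ...) {
  cat(sprintf("<metabolizer_params> HR.DM = %g, f.DM = %g\n",
              x$hr_dm, x$f_dm))
  invisible(x)
}

#' Base-case metabolizer parameters for a trial endpoint
#'
#' Returns the base case used throughout: HR.DM = 1.29 (DFS, BIG 1-98)
#' or 1.33 (EFS, ATAC), each with f.DM = 0.54.
#'
#' @param endpoint `"DFS"` or `"EFS"`, or a trial key accepted by
#'   [trial_schedule()] (`"big198"` maps to DFS, `"atac"` to EFS).
#' @return A [metabolizer_params()].
#' @export
base_case_params <- function(endpoint) {
  key <- toupper(endpoint)
  if (key %in% c("BIG198", "BIG1-98", "BIG 1-98")) key <- "DFS"
  if (key == "ATAC") key <- "EFS"
  switch(key,
         DFS = metabolizer_params(1.29, 0.54),
         EFS = metabolizer_params(1.33, 0.54),
         stop("unknown endpoint '", endpoint, "'; use 'DFS' or 'EFS'"))
}
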