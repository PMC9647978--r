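# Bridge to the bundled generic convex-programming oracle (SLSQP on an
# exact epigraph reformulation), used to verify the package's own solvers
# on small instances.

#' Solve a small penalized-regression instance with the bundled oracle
#'
#' Calls the generic convex-programming script shipped in
#' `inst/oracle/convex_oracle.py` through the system `python3`. Intended
#' for verification on toy instances, not production fitting.
#'
#' @param problem A list describing the instance. For `mode = "fused"`:
#'   `x` (list of per-time response vectors), `y` (list of per-time
#'   design matrices), `rho1`, `rho2`, `rho3`. For `mode = "mtg"`: `x`
#'   (times x genes matrix), `y` (list over genes of times x motifs
#'   matrices), `lam`.
#' @param python Python interpreter to use.
#' @return Parsed result list with `objective`, `theta`, and solver
#'   status fields.
#' @export
convex_oracle <- function(problem, python = "python3") {
  script <- system.file("oracle", "convex_oracle.py", package = "regdyn")
  if (!nzchar(script)) stop_bad_arg("bundled oracle script not found")
  if (!has_convex_oracle(python)) {
    stop_bad_arg("no usable python3 with numpy/scipy on PATH")
  }
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile))
  jsonlite::write_json(problem, infile, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  out <- system2(python, c(shQuote(script), shQuote(infile)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    stop_bad_arg("oracle failed (exit %d): %s", status,
                 paste(out, collapse = "\n"))
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = TRUE)
}

#' Is the bundled convex oracle usable on this machine?
#'
#' @param python Python interpreter to probe.
#' @return TRUE when `python3` with numpy and scipy is available.
#' @export
has_convex_oracle <- function(python = "python3") {
  if (!nzchar(Sys.which(python))) return(FALSE)
  code <- suppressWarnings(system2(python, c("-c", shQuote("import numpy, scipy")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}
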