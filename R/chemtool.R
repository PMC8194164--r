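#' @title Python/RDKit bridge
#' @description Internal helpers that shell out to the bundled RDKit script
#'   (`inst/python/chemtool.py`). All exchange is line-oriented JSON on
#'   temporary files, so a single call handles an arbitrary batch of
#'   molecules.
#' @name chemtool-bridge
#' @keywords internal
NULL

chemtool_script <- function() {
  path <- system.file("python", "chemtool.py", package = "targetfish")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled chemtool.py not found; is targetfish installed correctly?")
  }
  path
}

#' Locate the Python interpreter used for RDKit calls
#'
#' Resolution order: option `targetfish.python`, environment variable
#' `TARGETFISH_PYTHON`, then `python` / `python3` on PATH.
#' @return Path to the interpreter.
#' @keywords internal
python_binary <- function() {
  opt <- getOption("targetfish.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("TARGETFISH_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python", "python3")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) return(unname(hit))
  }
  stop("no python interpreter found; set options(targetfish.python = ...)")
}

#' Run a chemtool subcommand and collect its JSON-lines output
#' @param args Character vector of subcommand + flags.
#' @return List of parsed JSON records (one per output line).
#' @keywords internal
chemtool_run <- function(args) {
  out <- tempfile(fileext = ".jsonl")
  err <- tempfile(fileext = ".err")
  on.exit(unlink(c(out, err)), add = TRUE)
  status <- suppressWarnings(system2(
    python_binary(), c(shQuote(chemtool_script()), args),
    stdout = out, stderr = err
  ))
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("chemtool failed (exit ", status, "): ", msg)
  }
  lines <- readLines(out, warn = FALSE)
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Write SMILES strings to a temporary one-per-line file
#' @keywords internal
write_smiles_tmp <- function(smiles) {
  path <- tempfile(fileext = ".smi")
  writeLines(smiles, path)
  path
}
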