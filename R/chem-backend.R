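# Bridge to the RDKit helper script. All chemistry primitives that need a
# real toolkit (canonical SMILES, Morgan fingerprints, descriptors) run
# through one batched subprocess call; results are memoised per session so
# repeated featurization of the same structures is free.

python_binary <- function() {
  opt <- getOption("senoscreen.python", Sys.getenv("SENOSCREEN_PYTHON", ""))
  if (nzchar(opt)) return(opt)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found on PATH; set options(senoscreen.python=)",
       call. = FALSE)
}

rdkit_script <- function() {
  p <- system.file("python", "rdkit_tool.py", package = "senoscreen")
  if (!nzchar(p)) stop("rdkit_tool.py not found in installed package", call. = FALSE)
  p
}

# Run one subcommand of the helper on a character vector of SMILES.
# Returns the raw output lines (one per input, "ERROR\t..." on failure).
run_rdkit <- function(cmd, smiles, args = character()) {
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(smiles, infile)
  out <- suppressWarnings(system2(
    python_binary(), c(shQuote(rdkit_script()), cmd, shQuote(infile), args),
    stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed (exit ", status, ")", call. = FALSE)
  }
  if (length(out) != length(smiles)) {
    stop("chemistry backend returned ", length(out), " lines for ",
         length(smiles), " molecules", call. = FALSE)
  }
  out
}

# Memoised batched call: only SMILES not seen under this (cmd, key) are sent
# to the subprocess.
rdkit_cached <- function(cmd, smiles, args = character(), key = cmd) {
  cache_key <- paste0(key, "|", paste(args, collapse = " "))
  store <- .seno$cache[[cache_key]]
  if (is.null(store)) {
    store <- new.env(parent = emptyenv())
    .seno$cache[[cache_key]] <- store
  }
  res <- character(length(smiles))
  hit <- vapply(smiles, function(s) !is.null(store[[s]]), logical(1))
  if (any(hit)) res[hit] <- vapply(smiles[hit], function(s) store[[s]], character(1))
  todo <- unique(smiles[!hit])
  if (length(todo)) {
    out <- run_rdkit(cmd, todo, args)
    for (i in seq_along(todo)) store[[todo[i]]] <- out[i]
    res[!hit] <- vapply(smiles[!hit], function(s) store[[s]], character(1))
  }
  res
}

raise_parse_errors <- function(out, smiles) {
  bad <- startsWith(out, "ERROR\t")
  if (any(bad)) {
    offenders <- unique(smiles[bad])
    stop(structure(
      class = c("senoscreen_parse_error", "error", "condition"),
      list(message = paste0("unparseable SMILES: ",
                            paste(offenders, collapse = ", ")),
           call = NULL, smiles = offenders)
    ))
  }
  invisible(out)
}
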