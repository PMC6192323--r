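# structured conditions so the command-line wrapper can map error classes to
# exit codes (validation 2, QC refusal 3, I/O 4)
pcnvStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "pcnv_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

validationError <- function(fmt, ...) pcnvStop("pcnv_validation_error", fmt, ...)
qcError         <- function(fmt, ...) pcnvStop("pcnv_qc_error", fmt, ...)
ioError         <- function(fmt, ...) pcnvStop("pcnv_io_error", fmt, ...)

# population standard deviation; defined as 0 for a single value so that
# single-probe candidates can still be scored on ratio stability
popSD <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# chromosome-X recognition, tolerant of "chrX"/"X"/"x"
isChrX <- function(chrom) tolower(sub("^chr", "", as.character(chrom))) == "x"

# run an expression with a private RNG stream, leaving the caller's
# .Random.seed untouched
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}
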