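# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

# Residue key used everywhere a residue indexes a map: chain|resno|insert.
residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = "|")
}

# Run code with a private RNG stream so generators never disturb (or depend
# on) the caller's .Random.seed beyond their own `seed` argument.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# One-letter amino-acid codes for sequence-based pairing and mapping.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

aa_three_to_one <- function(res_names) {
  out <- unname(AA3TO1[toupper(res_names)])
  out[is.na(out)] <- "X"
  out
}

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

is_water_name <- function(res_names) toupper(res_names) %in% WATER_NAMES
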