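# shared helpers

# Render a shell bound the way feature names print it: one decimal when that
# is exact ("2.5", "6.0", "10.0"), full precision otherwise ("2.5001").
formatBound <- function(b) {
  vapply(b, function(x) {
    s <- sprintf("%.1f", x)
    if (abs(as.numeric(s) - x) < 1e-9) s else sprintf("%.10g", x)
  }, "")
}

# C-locale, platform-stable sort
sortC <- function(x) sort(x, method = "radix")

pkgAsset <- function(file) {
  path <- system.file("extdata", file, package = "msecif", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("packaged asset '", file, "' is missing or corrupt", call. = FALSE)
  path
}

.msecifCache <- new.env(parent = emptyenv())
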