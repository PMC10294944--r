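#' @useDynLib ctgnet, .registration = TRUE
.onLoad <- function(libname, pkgname) {
  # The network layers multiply many small dense matrices; multi-threaded
  # BLAS spends more time synchronising than computing at these sizes.
  if (!nzchar(Sys.getenv("OPENBLAS_NUM_THREADS")))
    Sys.setenv(OPENBLAS_NUM_THREADS = "1")
  .Call(ctgnet_set_blas_threads, 1L)
}

#' Set the number of BLAS threads
#'
#' The layer arithmetic is dominated by many small dense products, for
#' which a single BLAS thread is fastest; the package pins one thread on
#' load. Call this to restore parallel BLAS for other workloads.
#'
#' @param n thread count.
#' @return \code{NULL}, invisibly.
#' @export
setBlasThreads <- function(n) {
  invisible(.Call(ctgnet_set_blas_threads, as.integer(n)))
}
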