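/* Cap the BLAS thread pool at run time. The network layers issue many
 * small dense products for which multi-threaded BLAS synchronisation
 * costs far more than the arithmetic; the environment variable route is
 * unavailable once the BLAS library has been loaded. No-op when the
 * running BLAS does not expose a thread-control entry point. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#ifndef _WIN32
#include <dlfcn.h>
#endif

SEXP ctgnet_set_blas_threads(SEXP n)
{
#ifndef _WIN32
    void (*setter)(int) = NULL;
    setter = (void (*)(int)) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
    if (setter == NULL)
        setter = (void (*)(int)) dlsym(RTLD_DEFAULT, "goto_set_num_threads");
    if (setter != NULL)
        setter(asInteger(n));
#endif
    return R_NilValue;
}

SEXP ctgnet_lstm_forward(SEXP Zx_, SEXP Wh_, SEXP b_, SEXP dims_);
SEXP ctgnet_lstm_backward(SEXP dY_, SEXP Hs_, SEXP Cs_, SEXP TC_, SEXP G_,
                          SEXP Wh_, SEXP dims_, SEXP retseq_);
SEXP ctgnet_maxpool1d_forward(SEXP X_);
SEXP ctgnet_maxpool1d_backward(SEXP dY_, SEXP sel_, SEXP dims_);
SEXP ctgnet_im2col1d(SEXP X_, SEXP k_, SEXP pad_);
SEXP ctgnet_col2im1d(SEXP dM_, SEXP k_, SEXP pad_, SEXP dims_);

static const R_CallMethodDef callMethods[] = {
    {"ctgnet_set_blas_threads", (DL_FUNC) &ctgnet_set_blas_threads, 1},
    {"ctgnet_lstm_forward", (DL_FUNC) &ctgnet_lstm_forward, 4},
    {"ctgnet_lstm_backward", (DL_FUNC) &ctgnet_lstm_backward, 8},
    {"ctgnet_maxpool1d_forward", (DL_FUNC) &ctgnet_maxpool1d_forward, 1},
    {"ctgnet_maxpool1d_backward", (DL_FUNC) &ctgnet_maxpool1d_backward, 3},
    {"ctgnet_im2col1d", (DL_FUNC) &ctgnet_im2col1d, 3},
    {"ctgnet_col2im1d", (DL_FUNC) &ctgnet_col2im1d, 4},
    {NULL, NULL, 0}
};

void R_init_ctgnet(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
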