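/* 1D max pooling (width 2, floor semantics) over (B, T, C) arrays. */
#include <R.h>
#include <Rinternals.h>
#include <string.h>

SEXP ctgnet_maxpool1d_forward(SEXP X_)
{
    const int *xd = INTEGER(getAttrib(X_, R_DimSymbol));
    const int B = xd[0], T = xd[1], C = xd[2], To = T / 2;
    const double *X = REAL(X_);

    SEXP out_ = PROTECT(alloc3DArray(REALSXP, B, To, C));
    SEXP sel_ = PROTECT(alloc3DArray(LGLSXP, B, To, C));
    double *out = REAL(out_);
    int *sel = LOGICAL(sel_);

    for (int c = 0; c < C; c++) {
        const double *xc = X + (size_t) c * B * T;
        double *oc = out + (size_t) c * B * To;
        int *sc = sel + (size_t) c * B * To;
        for (int t = 0; t < To; t++) {
            const double *a = xc + (size_t) (2 * t) * B;
            const double *b = a + B;
            double *o = oc + (size_t) t * B;
            int *s = sc + (size_t) t * B;
            for (int i = 0; i < B; i++) {
                int takeA = a[i] >= b[i];
                o[i] = takeA ? a[i] : b[i];
                s[i] = takeA;
            }
        }
    }
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, out_);
    SET_VECTOR_ELT(res, 1, sel_);
    UNPROTECT(3);
    return res;
}

SEXP ctgnet_maxpool1d_backward(SEXP dY_, SEXP sel_, SEXP dims_)
{
    const int B = INTEGER(dims_)[0], T = INTEGER(dims_)[1],
              C = INTEGER(dims_)[2], To = T / 2;
    const double *dY = REAL(dY_);
    const int *sel = LOGICAL(sel_);

    SEXP dX_ = PROTECT(alloc3DArray(REALSXP, B, T, C));
    double *dX = REAL(dX_);
    memset(dX, 0, (size_t) B * T * C * sizeof(double));

    for (int c = 0; c < C; c++) {
        const double *gc = dY + (size_t) c * B * To;
        const int *sc = sel + (size_t) c * B * To;
        double *xc = dX + (size_t) c * B * T;
        for (int t = 0; t < To; t++) {
            const double *g = gc + (size_t) t * B;
            const int *s = sc + (size_t) t * B;
            double *a = xc + (size_t) (2 * t) * B;
            double *b = a + B;
            for (int i = 0; i < B; i++) {
                if (s[i]) a[i] = g[i]; else b[i] = g[i];
            }
        }
    }
    UNPROTECT(1);
    return dX_;
}
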