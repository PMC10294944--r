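/* im2col / col2im for 1D 'same' convolutions.
 *
 * X is a (B, T, C) column-major array; the column matrix M is (B*T) x
 * (k*C) with rows batch-major within timestep and columns grouped by tap
 * then channel, matching the weight layout W (k*C x Cout). */
#include <R.h>
#include <Rinternals.h>
#include <string.h>

SEXP ctgnet_im2col1d(SEXP X_, SEXP k_, SEXP pad_)
{
    const int *xd = INTEGER(getAttrib(X_, R_DimSymbol));
    const int B = xd[0], T = xd[1], C = xd[2];
    const int k = asInteger(k_), pad = asInteger(pad_);
    const double *X = REAL(X_);
    const size_t BT = (size_t) B * T;

    SEXP M_ = PROTECT(allocMatrix(REALSXP, BT, (size_t) k * C));
    double *M = REAL(M_);
    memset(M, 0, BT * (size_t) k * C * sizeof(double));

    for (int j = 0; j < k; j++) {
        for (int c = 0; c < C; c++) {
            double *mcol = M + ((size_t) j * C + c) * BT;
            const double *xcol = X + (size_t) c * BT;
            for (int t = 0; t < T; t++) {
                int ts = t + j - pad;    /* source timestep */
                if (ts < 0 || ts >= T) continue;
                memcpy(mcol + (size_t) t * B, xcol + (size_t) ts * B,
                       B * sizeof(double));
            }
        }
    }
    UNPROTECT(1);
    return M_;
}

SEXP ctgnet_col2im1d(SEXP dM_, SEXP k_, SEXP pad_, SEXP dims_)
{
    const int B = INTEGER(dims_)[0], T = INTEGER(dims_)[1],
              C = INTEGER(dims_)[2];
    const int k = asInteger(k_), pad = asInteger(pad_);
    const double *dM = REAL(dM_);
    const size_t BT = (size_t) B * T;

    SEXP dX_ = PROTECT(alloc3DArray(REALSXP, B, T, C));
    double *dX = REAL(dX_);
    memset(dX, 0, BT * (size_t) C * sizeof(double));

    for (int j = 0; j < k; j++) {
        for (int c = 0; c < C; c++) {
            const double *mcol = dM + ((size_t) j * C + c) * BT;
            double *xcol = dX + (size_t) c * BT;
            for (int t = 0; t < T; t++) {
                int ts = t + j - pad;
                if (ts < 0 || ts >= T) continue;
                const double *src = mcol + (size_t) t * B;
                double *dst = xcol + (size_t) ts * B;
                for (int b = 0; b < B; b++) dst[b] += src[b];
            }
        }
    }
    UNPROTECT(1);
    return dX_;
}
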