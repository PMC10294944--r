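/* LSTM recurrence, forward and backward-through-time.
 *
 * The input projection (x_t %*% Wx) is precomputed in R as one large
 * matrix product; the bias and the sequential recurrence live here, with
 * the per-step dense products delegated to BLAS. Matrices are
 * column-major doubles. Zx is (B*T) x 4U with rows batch-major within
 * timestep (row (t-1)*B + b holds sample b at time t); gate order along
 * the 4U axis is input, forget, candidate, output. The forward pass also
 * returns tanh(c_t), reused by the backward pass. */
#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <math.h>
#include <string.h>

static double sigm(double x) { return 1.0 / (1.0 + exp(-x)); }

SEXP ctgnet_lstm_forward(SEXP Zx_, SEXP Wh_, SEXP b_, SEXP dims_)
{
    const int B = INTEGER(dims_)[0], T = INTEGER(dims_)[1],
              U = INTEGER(dims_)[2];
    const double *Zx = REAL(Zx_), *Wh = REAL(Wh_), *bias = REAL(b_);
    const size_t BT = (size_t) B * T, BU = (size_t) B * U;
    const double one = 1.0;

    SEXP Hs_ = PROTECT(allocMatrix(REALSXP, BT, U));
    SEXP Cs_ = PROTECT(allocMatrix(REALSXP, BT, U));
    SEXP TC_ = PROTECT(allocMatrix(REALSXP, BT, U));
    SEXP G_ = PROTECT(allocMatrix(REALSXP, BT, 4 * U));
    double *Hs = REAL(Hs_), *Cs = REAL(Cs_), *TC = REAL(TC_), *G = REAL(G_);

    double *z = (double *) R_alloc(4 * BU, sizeof(double));
    double *h_prev = (double *) R_alloc(BU, sizeof(double));
    double *c_prev = (double *) R_alloc(BU, sizeof(double));
    memset(h_prev, 0, BU * sizeof(double));
    memset(c_prev, 0, BU * sizeof(double));
    const int fourU = 4 * U;

    for (int t = 0; t < T; t++) {
        size_t row0 = (size_t) t * B;
        for (int j = 0; j < fourU; j++) {
            const double *src = Zx + (size_t) j * BT + row0;
            double *dst = z + (size_t) j * B;
            double bj = bias[j];
            for (int b = 0; b < B; b++) dst[b] = src[b] + bj;
        }
        /* z += h_prev (B x U) %*% Wh (U x 4U) */
        {
            int iB = B, iU = U, i4U = fourU;
            F77_CALL(dgemm)("N", "N", &iB, &i4U, &iU, &one, h_prev, &iB,
                            Wh, &iU, &one, z, &iB FCONE FCONE);
        }
        for (int u = 0; u < U; u++) {
            double *zi = z + (size_t) u * B;
            double *zf = z + (size_t) (U + u) * B;
            double *zg = z + (size_t) (2 * U + u) * B;
            double *zo = z + (size_t) (3 * U + u) * B;
            double *hcol = h_prev + (size_t) u * B;
            double *ccol = c_prev + (size_t) u * B;
            size_t out = (size_t) u * BT + row0;
            for (int b = 0; b < B; b++) {
                double gi = sigm(zi[b]), gf = sigm(zf[b]);
                double gg = tanh(zg[b]), go = sigm(zo[b]);
                double c = gf * ccol[b] + gi * gg;
                double tc = tanh(c);
                double h = go * tc;
                G[out + b] = gi;
                G[(size_t) U * BT + out + b] = gf;
                G[(size_t) 2 * U * BT + out + b] = gg;
                G[(size_t) 3 * U * BT + out + b] = go;
                Cs[out + b] = c;
                TC[out + b] = tc;
                Hs[out + b] = h;
                ccol[b] = c;
                hcol[b] = h;
            }
        }
    }
    SEXP out = PROTECT(allocVector(VECSXP, 4));
    SET_VECTOR_ELT(out, 0, Hs_);
    SET_VECTOR_ELT(out, 1, Cs_);
    SET_VECTOR_ELT(out, 2, TC_);
    SET_VECTOR_ELT(out, 3, G_);
    UNPROTECT(5);
    return out;
}

SEXP ctgnet_lstm_backward(SEXP dY_, SEXP Hs_, SEXP Cs_, SEXP TC_, SEXP G_,
                          SEXP Wh_, SEXP dims_, SEXP retseq_)
{
    const int B = INTEGER(dims_)[0], T = INTEGER(dims_)[1],
              U = INTEGER(dims_)[2];
    const int retseq = asLogical(retseq_);
    const double *dY = REAL(dY_), *Hs = REAL(Hs_), *Cs = REAL(Cs_),
                 *TC = REAL(TC_), *G = REAL(G_), *Wh = REAL(Wh_);
    const size_t BT = (size_t) B * T, BU = (size_t) B * U;
    const double one = 1.0, zero = 0.0;
    const int fourU = 4 * U;

    SEXP dZ_ = PROTECT(allocMatrix(REALSXP, BT, fourU));
    SEXP dWh_ = PROTECT(allocMatrix(REALSXP, U, fourU));
    double *dZbig = REAL(dZ_), *dWh = REAL(dWh_);
    memset(dWh, 0, (size_t) U * fourU * sizeof(double));

    double *dh = (double *) R_alloc(BU, sizeof(double));
    double *dc = (double *) R_alloc(BU, sizeof(double));
    double *dz = (double *) R_alloc(4 * BU, sizeof(double));
    memset(dh, 0, BU * sizeof(double));
    memset(dc, 0, BU * sizeof(double));

    for (int t = T - 1; t >= 0; t--) {
        size_t row0 = (size_t) t * B;
        if (retseq) {
            for (int u = 0; u < U; u++) {
                const double *col = dY + (size_t) u * BT + row0;
                double *dhcol = dh + (size_t) u * B;
                for (int b = 0; b < B; b++) dhcol[b] += col[b];
            }
        } else if (t == T - 1) {
            for (size_t k = 0; k < BU; k++) dh[k] += dY[k];
        }
        for (int u = 0; u < U; u++) {
            size_t in = (size_t) u * BT + row0;
            const double *gi = G + in;
            const double *gf = G + (size_t) U * BT + in;
            const double *gg = G + (size_t) 2 * U * BT + in;
            const double *go = G + (size_t) 3 * U * BT + in;
            const double *tcv = TC + in;
            double *dhcol = dh + (size_t) u * B;
            double *dccol = dc + (size_t) u * B;
            double *dzi = dz + (size_t) u * B;
            double *dzf = dz + (size_t) (U + u) * B;
            double *dzg = dz + (size_t) (2 * U + u) * B;
            double *dzo = dz + (size_t) (3 * U + u) * B;
            for (int b = 0; b < B; b++) {
                double tc = tcv[b];
                double cp = (t > 0) ? Cs[in + b - B] : 0.0;
                double dcv = dccol[b] + dhcol[b] * go[b] * (1.0 - tc * tc);
                dzi[b] = dcv * gg[b] * gi[b] * (1.0 - gi[b]);
                dzf[b] = dcv * cp * gf[b] * (1.0 - gf[b]);
                dzg[b] = dcv * gi[b] * (1.0 - gg[b] * gg[b]);
                dzo[b] = dhcol[b] * tc * go[b] * (1.0 - go[b]);
                dccol[b] = dcv * gf[b];
                dhcol[b] = 0.0;          /* rebuilt from dz below */
            }
        }
        if (t > 0) {
            /* dWh += t(h_prev) %*% dz ; dh_prev = dz %*% t(Wh) */
            int iB = B, iU = U, i4U = fourU, iBT = (int) BT;
            F77_CALL(dgemm)("T", "N", &iU, &i4U, &iB, &one, Hs + row0 - B,
                            &iBT, dz, &iB, &one, dWh, &iU FCONE FCONE);
            F77_CALL(dgemm)("N", "T", &iB, &iU, &i4U, &one, dz, &iB,
                            Wh, &iU, &zero, dh, &iB FCONE FCONE);
        }
        for (int j = 0; j < fourU; j++)
            memcpy(dZbig + (size_t) j * BT + row0, dz + (size_t) j * B,
                   B * sizeof(double));
    }
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, dZ_);
    SET_VECTOR_ELT(out, 1, dWh_);
    UNPROTECT(3);
    return out;
}
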