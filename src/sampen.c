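#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* Template-match counts for sample entropy (Richman & Moorman).
   B = #{i<j <= n-m : max_{k<m} |x[i+k]-x[j+k]| <= r}
   A = the same with (m+1)-length templates (same i,j range);
   self-matches excluded. Returned as c(B, A). */
SEXP C_sampen_counts(SEXP xs, SEXP ms, SEXP rs)
{
    const double *x = REAL(xs);
    const int n = LENGTH(xs);
    const int m = asInteger(ms);
    const double r = asReal(rs);
    const int nt = n - m;
    double A = 0.0, B = 0.0;

    for (int i = 0; i < nt - 1; i++) {
        for (int j = i + 1; j < nt; j++) {
            int match = 1;
            for (int k = 0; k < m; k++) {
                if (fabs(x[i + k] - x[j + k]) > r) { match = 0; break; }
            }
            if (!match) continue;
            B += 1.0;
            if (fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
        }
    }
    SEXP out = PROTECT(allocVector(REALSXP, 2));
    REAL(out)[0] = B;
    REAL(out)[1] = A;
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_sampen_counts", (DL_FUNC) &C_sampen_counts, 3},
    {NULL, NULL, 0}
};

void R_init_lsdlspectra(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
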