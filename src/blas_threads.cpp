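#include <Rcpp.h>

#ifndef _WIN32
#include <dlfcn.h>
#endif

// Pin the BLAS thread pool. The separable convolutions are many small
// matrix products; on a single-core host a spinning OpenBLAS pool slows
// them several-fold. Resolved dynamically so non-OpenBLAS builds are a
// no-op.
// [[Rcpp::export]]
bool cpp_set_blas_threads(int n) {
#ifndef _WIN32
    typedef void (*setter)(int);
    setter f = (setter)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
    if (f != NULL) {
        f(n);
        return true;
    }
#endif
    return false;
}
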